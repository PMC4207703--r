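# run expr with a fixed RNG seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# lognormal sdlog corresponding to a real-space coefficient of variation
cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

pkg_version <- function() {
  as.character(utils::packageVersion("calcross"))
}
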