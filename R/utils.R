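# internal helpers

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# 3D rotation matrix: angle theta about unit axis u (Rodrigues).
rotation_matrix <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  K <- matrix(c(0, uz, -uy, -uz, 0, ux, uy, -ux, 0), 3L, 3L)
  diag(3L) * ct + st * K + (1 - ct) * tcrossprod(u)
}

# random unit vector
runit3 <- function() {
  z <- stats::runif(1L, -1, 1)
  ph <- stats::runif(1L, 0, 2 * pi)
  rr <- sqrt(max(0, 1 - z^2))
  c(rr * cos(ph), rr * sin(ph), z)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
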