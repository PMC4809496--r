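# Shared fixture builders; everything is generated in code.

make_ts <- function(t, y) tibble::tibble(time = t, value = y)

# Deterministic irregular sampling times over a window.
irregular_times <- function(n, from = 1999, to = 2015, seed = 1) {
  withr::with_seed(seed, sort(runif(n, from, to)))
}

# A 5-pixel valid cross centred in an invalid grid.
cross_mask <- function(nr = 9, nc = 9) {
  m <- matrix(FALSE, nr, nc)
  r <- (nr + 1) %/% 2; cc <- (nc + 1) %/% 2
  m[r, cc] <- TRUE
  m[r - 1, cc] <- m[r + 1, cc] <- m[r, cc - 1] <- m[r, cc + 1] <- TRUE
  m
}

# The cross grown by one 4-connected pixel: a 6-pixel cluster.
cross6_mask <- function() {
  m <- cross_mask()
  m[6, 6] <- TRUE  # touches the (6, 5) arm
  m
}

# Small scene used across mapping tests (cached per session).
small_scene <- local({
  sc <- NULL
  function() {
    if (is.null(sc)) {
      sc <<- generate_scene(10, 10, n_dates = 40,
                            sampling = sampling_model(seed = 404))
    }
    sc
  }
})
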