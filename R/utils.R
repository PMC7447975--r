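# Small shared helpers.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific child seed from a master seed (kept < 2^31).
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + stream * 104729) %% 2147483647
}

#' Quinquennial age groups
#'
#' Cuts ages into the 5-year bands used for survey stratification and
#' standardization ("05-09" through "85+"; under-5s are not part of the
#' study population).
#'
#' @param age numeric vector of ages in years.
#' @return factor of age-band labels.
#' @export
age_to_group <- function(age) {
  breaks <- c(seq(5, 85, by = 5), Inf)
  labs <- c(sprintf("%02d-%02d", seq(5, 80, 5), seq(9, 84, 5)), "85+")
  cut(age, breaks = breaks, labels = labs, right = FALSE)
}

#' All quinquennial age-group labels
#' @return character vector of the 17 labels from "05-09" to "85+".
#' @export
age_group_levels <- function() {
  c(sprintf("%02d-%02d", seq(5, 80, 5), seq(9, 84, 5)), "85+")
}

# Uniform points inside a polygon by rejection from its bounding box.
runif_in_polygon <- function(n, poly) {
  bb <- apply(poly, 2, range)
  out <- matrix(numeric(0), ncol = 2)
  guard <- 0L
  while (nrow(out) < n && guard < 1000L) {
    m <- max(2L * (n - nrow(out)), 16L)
    px <- stats::runif(m, bb[1, 1], bb[2, 1])
    py <- stats::runif(m, bb[1, 2], bb[2, 2])
    keep <- point_in_polygon(px, py, poly, tol = 0)
    out <- rbind(out, cbind(px[keep], py[keep]))
    guard <- guard + 1L
  }
  if (nrow(out) < n) stop("rejection sampling failed: degenerate polygon?")
  out[seq_len(n), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
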