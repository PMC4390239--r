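#' @keywords internal
"_PACKAGE"

#' @importFrom stats pchisq pnorm quantile rbinom rlnorm rnorm runif sd setNames
#' @importFrom utils combn read.csv write.csv packageVersion
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

# Sequential labels A, B, ..., Z, AA, AB, ... (base-26, bijective)
community_labels <- function(n) {
  lab <- character(n)
  for (i in seq_len(n)) {
    k <- i
    s <- ""
    while (k > 0) {
      r <- (k - 1L) %% 26L
      s <- paste0(LETTERS[r + 1L], s)
      k <- (k - 1L) %/% 26L
    }
    lab[i] <- s
  }
  lab
}

# Deterministic sub-seed derivation; keeps values in 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483647)
}

stop_domain <- function(...) stop(..., call. = FALSE)

# add a constant column to a data.frame, working also for 0-row frames
add_column <- function(df, col, value) {
  df[[col]] <- rep(value, nrow(df))
  df
}
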