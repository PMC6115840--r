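#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves rounded up (away from
#' zero), the convention used when reporting window-count percentages.
#' Base [round()] uses round-half-even, which would turn 5.65 into 5.6;
#' the reporting convention here turns it into 5.7.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(574 / 10338 * 100, 1)  # 5.6
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

# fraction -> percent to one decimal, half-up (reporting convention)
percent_one_decimal <- function(frac) round_half_up(100 * frac, 1)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards. seed = NULL leaves RNG alone.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

check_file_exists <- function(path, what = "input file") {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop(what, " not found: ", path, call. = FALSE)
  invisible(path)
}
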