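#' Construct a growth table of single- and mixed-substrate rates
#'
#' The data model of a mixed-substrate growth study: one steady-state
#' exponential growth rate per single substrate, and one per unordered
#' substrate pair, with each pair labelled group `"A"` (expected to follow the
#' co-utilization null model) or `"B"` (known extra uptake interactions such
#' as inducer exclusion or FBP feedback inhibition).
#'
#' @param singles data frame with columns `substrate` (character, unique) and
#'   `rate_per_h` (positive numeric).
#' @param pairs data frame with columns `substrate_1`, `substrate_2`
#'   (characters referencing `singles$substrate`), `rate_per_h` (positive
#'   numeric) and `group` (`"A"` or `"B"`).
#' @param dedup drop repeated unordered pairs (keeping the first occurrence)
#'   with a warning instead of failing validation.
#' @return an object of class `growth_table`: a list with elements `singles`
#'   and `pairs` as validated data frames.
#' @seealso [read_growth_table()], [builtin_table1()], [predict_pairs()]
#' @export
growth_table <- function(singles, pairs, dedup = TRUE) {
  singles <- as.data.frame(singles, stringsAsFactors = FALSE)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  need_s <- c("substrate", "rate_per_h")
  need_p <- c("substrate_1", "substrate_2", "rate_per_h", "group")
  if (!all(need_s %in% names(singles))) {
    stop_validation("`singles` must have columns %s",
                    paste(need_s, collapse = ", "))
  }
  if (!all(need_p %in% names(pairs))) {
    stop_validation("`pairs` must have columns %s",
                    paste(need_p, collapse = ", "))
  }
  singles <- singles[need_s]
  pairs <- pairs[need_p]
  singles$substrate <- as.character(singles$substrate)
  pairs$substrate_1 <- as.character(pairs$substrate_1)
  pairs$substrate_2 <- as.character(pairs$substrate_2)
  pairs$group <- as.character(pairs$group)

  if (anyDuplicated(singles$substrate)) {
    stop_validation("duplicate substrate in `singles`: %s",
                    singles$substrate[duplicated(singles$substrate)][1L])
  }
  check_positive_rate(singles$rate_per_h, "singles")
  check_positive_rate(pairs$rate_per_h, "pairs")
  if (!all(pairs$group %in% c("A", "B"))) {
    stop_validation("pair group labels must be \"A\" or \"B\"")
  }
  unknown <- setdiff(c(pairs$substrate_1, pairs$substrate_2),
                     singles$substrate)
  if (length(unknown)) {
    stop_validation("pair references undeclared substrate \"%s\"", unknown[1L])
  }
  if (any(pairs$substrate_1 == pairs$substrate_2)) {
    stop_validation("a pair must involve two distinct substrates")
  }

  key <- unordered_pair_key(pairs$substrate_1, pairs$substrate_2)
  if (anyDuplicated(key)) {
    if (!dedup) {
      stop_validation("unordered pair %s appears more than once",
                      key[duplicated(key)][1L])
    }
    dup <- duplicated(key)
    warning(sprintf("dropping %d duplicate unordered pair(s): %s",
                    sum(dup), paste(unique(key[dup]), collapse = ", ")),
            call. = FALSE)
    pairs <- pairs[!dup, , drop = FALSE]
  }
  rownames(singles) <- NULL
  rownames(pairs) <- NULL
  structure(list(singles = singles, pairs = pairs), class = "growth_table")
}

unordered_pair_key <- function(s1, s2) {
  paste(pmin(s1, s2), pmax(s1, s2), sep = "+")
}

check_positive_rate <- function(x, where) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop_validation("growth rates in `%s` must be finite and > 0 (1/h)", where)
  }
}

#' @export
print.growth_table <- function(x, ...) {
  cat(sprintf("<growth_table> %d substrates, %d pairs (%d group A, %d group B)\n",
              nrow(x$singles), nrow(x$pairs),
              sum(x$pairs$group == "A"), sum(x$pairs$group == "B")))
  cat("singles:\n")
  print(x$singles, row.names = FALSE)
  cat("pairs:\n")
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Read a growth table from singles/pairs CSV files
#'
#' The on-disk dialect is two UTF-8 CSV files with headers and decimal-point
#' reals: `singles` with columns `substrate,rate_per_h` and `pairs` with
#' columns `substrate_1,substrate_2,rate_per_h,group`. Repeated unordered
#' pairs are dropped (first kept) with a warning. Malformed rows are reported
#' with their line number.
#'
#' @param singles_path path to the singles CSV.
#' @param pairs_path path to the pairs CSV.
#' @return a validated [growth_table()].
#' @export
read_growth_table <- function(singles_path, pairs_path) {
  singles <- read_checked_csv(singles_path, c("substrate", "rate_per_h"))
  pairs <- read_checked_csv(pairs_path,
                            c("substrate_1", "substrate_2", "rate_per_h",
                              "group"))
  growth_table(singles, pairs)
}

read_checked_csv <- function(path, columns) {
  if (!file.exists(path)) {
    stop_validation("file not found: %s", path)
  }
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                 fileEncoding = "UTF-8")
  if (!identical(names(df)[seq_along(columns)], columns)) {
    stop_validation("%s: malformed header, expected \"%s\"", path,
                    paste(columns, collapse = ","))
  }
  rate <- suppressWarnings(as.numeric(df$rate_per_h))
  bad <- which(is.na(rate) | !is.finite(rate))
  if (length(bad)) {
    stop_validation("%s line %d: non-numeric rate \"%s\"", path,
                    bad[1L] + 1L, df$rate_per_h[bad[1L]])
  }
  if (any(rate <= 0)) {
    bad <- which(rate <= 0)[1L]
    stop_validation("%s line %d: rate must be > 0, got %s", path, bad + 1L,
                    df$rate_per_h[bad])
  }
  df$rate_per_h <- rate
  df
}

#' Write a growth table to singles/pairs CSV files
#'
#' Rates are written at 15 significant digits so that a write/read round trip
#' is lossless.
#'
#' @param table a [growth_table()].
#' @param singles_path,pairs_path output CSV paths.
#' @return the input `table`, invisibly.
#' @export
write_growth_table <- function(table, singles_path, pairs_path) {
  stopifnot(inherits(table, "growth_table"))
  s <- table$singles
  p <- table$pairs
  s$rate_per_h <- format(s$rate_per_h, digits = 15, trim = TRUE,
                         scientific = FALSE)
  p$rate_per_h <- format(p$rate_per_h, digits = 15, trim = TRUE,
                         scientific = FALSE)
  write.csv(s, singles_path, row.names = FALSE, quote = FALSE)
  write.csv(p, pairs_path, row.names = FALSE, quote = FALSE)
  invisible(table)
}

#' The published single- and mixed-substrate growth-rate table
#'
#' Steady-state exponential growth rates of *E. coli* K-12 NCM3722 in minimal
#' medium with one or two saturating carbon substrates: 8 single substrates,
#' 15 group-A pairs (one "lower" substrate — succinate, pyruvate or
#' oxaloacetate — combined with one "upper" substrate) and 7 unique group-B
#' pairs (glucose or glycerol combined with other upper substrates, where
#' inducer exclusion or FBP feedback inhibition acts outside the
#' co-utilization null model; glucose+glycerol is counted once). Values are
#' the printed 2-decimal averages over 2–4 experiments with between-experiment
#' variability of order 5%.
#'
#' @return a [growth_table()] with 8 substrates and 22 pairs.
#' @examples
#' tab <- builtin_table1()
#' subset(tab$singles, substrate == "glucose")
#' @export
builtin_table1 <- function() {
  read_growth_table(
    system.file("extdata", "table1_singles.csv", package = "crpgrowth",
                mustWork = TRUE),
    system.file("extdata", "table1_pairs.csv", package = "crpgrowth",
                mustWork = TRUE))
}
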