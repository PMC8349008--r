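#' Expand an ICD-10 three-character prefix range
#'
#' Mapping files may give either a single prefix (`"F20"`) or an inclusive
#' range over the numeric part (`"F20-F29"`); ranges must stay within one
#' letter chapter.
#'
#' @param x character vector of prefixes and/or ranges.
#' @return character vector of individual three-character prefixes.
#' @export
#' @examples
#' expand_icd_prefixes(c("F20-F23", "F31"))
expand_icd_prefixes <- function(x) {
  out <- lapply(x, function(tok) {
    tok <- toupper(trimws(tok))
    if (!grepl("-", tok, fixed = TRUE)) return(tok)
    parts <- strsplit(tok, "-", fixed = TRUE)[[1]]
    stopifnot(length(parts) == 2L)
    ch1 <- substr(parts[1], 1, 1)
    ch2 <- substr(parts[2], 1, 1)
    if (ch1 != ch2) stop("ICD prefix range must stay in one chapter: ", tok)
    lo <- as.integer(substr(parts[1], 2, 3))
    hi <- as.integer(substr(parts[2], 2, 3))
    sprintf("%s%02d", ch1, lo:hi)
  })
  unlist(out, use.names = FALSE)
}

#' Expand a procedure-code set specification
#'
#' Numeric CPT ranges (`"99201-99499"`) are kept as ranges and matched
#' numerically; other tokens are matched as literal codes.
#'
#' @param codeset character vector of codes and/or numeric ranges.
#' @return a predicate function over character procedure codes.
#' @keywords internal
procedure_code_matcher <- function(codeset) {
  is_range <- grepl("^[0-9]+-[0-9]+$", codeset)
  ranges <- lapply(codeset[is_range], function(tok) {
    as.numeric(strsplit(tok, "-", fixed = TRUE)[[1]])
  })
  literals <- codeset[!is_range]
  function(codes) {
    hit <- codes %in% literals
    num <- suppressWarnings(as.numeric(codes))
    for (r in ranges) {
      hit <- hit | (!is.na(num) & num >= r[1] & num <= r[2])
    }
    hit & !is.na(codes) & nzchar(codes)
  }
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 means identical up to relabeling, 0 is the expected value under random
#' association.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return a single number in (-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

pair_key <- function(i, j) {
  paste(pmin(i, j), pmax(i, j), sep = "_")
}
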