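#' Define a target system: a multiset of target strings
#'
#' A target system collects the strings whose joint construction cost is of
#' interest, with a count per string.  A single string is the size-1 case.
#' Repeated blocks may be shared across members, but member strings are not
#' connected: no reused block ever spans a member boundary.
#'
#' @param strings character vector of non-empty target strings.
#' @param counts integer vector of per-string counts (recycled); duplicate
#'   strings accumulate their counts.
#' @param basic optional [basic_set()]; when supplied, every member must be
#'   tokenizable over it or construction fails.
#' @return An object of class `lp_target_system`: a data frame with columns
#'   `string` and `count`.
#' @examples
#' target_system("ABCDBCDBCDCDEFEF")
#' target_system(c("ABDEDBED", "ABDED", "ABDABD", "CAB", "ED"),
#'               counts = c(2, 1, 1, 2, 3))
#' @export
target_system <- function(strings, counts = 1L, basic = NULL) {
  strings <- as.character(strings)
  if (anyNA(strings))
    stop("target strings must not be NA", call. = FALSE)
  if (any(!nzchar(strings)))
    stop("target strings must be non-empty", call. = FALSE)
  counts <- rep_len(as.integer(counts), length(strings))
  if (anyNA(counts) || any(counts < 1L))
    stop("counts must be positive integers", call. = FALSE)
  agg <- tapply(counts, strings, sum)
  df <- data.frame(string = names(agg), count = as.integer(agg),
                   stringsAsFactors = FALSE, row.names = NULL)
  df <- df[order(df$string, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  ts <- structure(df, class = c("lp_target_system", "data.frame"))
  if (!is.null(basic)) {
    for (s in ts$string) lp_tokenize(s, basic, what = s)  # errors if not coverable
  }
  ts
}

is_target_system <- function(x) inherits(x, "lp_target_system")

## coerce loose inputs (a character vector, possibly with duplicates)
as_target_system <- function(x, basic = NULL) {
  if (is_target_system(x)) {
    if (!is.null(basic))
      for (s in x$string) lp_tokenize(s, basic, what = s)
    return(x)
  }
  target_system(x, basic = basic)
}

#' @export
print.lp_target_system <- function(x, ...) {
  cat("Target system:", sum(x$count), "instance(s) of",
      nrow(x), "distinct string(s)\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %s%s\n", x$string[i],
                if (x$count[i] > 1L) sprintf("  (x%d)", x$count[i]) else ""))
  invisible(x)
}

## total number of target instances (take-out lifts)
lp_n_instances <- function(target) sum(target$count)

#' Read targets from a plain-text or FASTA file
#'
#' The `lines` format holds one target per line, `STRING` or
#' `STRING<TAB>count`.  The `fasta` format reads sequences with
#' `Biostrings` when available (falling back to a minimal reader);
#' duplicated sequences accumulate multiplicity.
#'
#' @param path input file path.
#' @param format `"lines"` or `"fasta"`.
#' @return An `lp_target_system`.
#' @export
read_targets <- function(path, format = c("lines", "fasta")) {
  format <- match.arg(format)
  if (format == "fasta") {
    seqs <- lp_read_fasta(path)
    if (length(seqs) == 0L)
      stop("no sequences found in ", path, call. = FALSE)
    return(target_system(seqs))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(structure(data.frame(string = character(0), count = integer(0),
                                stringsAsFactors = FALSE),
                     class = c("lp_target_system", "data.frame")))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  strings <- vapply(parts, `[[`, "", 1L)
  counts <- vapply(parts, function(p) {
    if (length(p) >= 2L) {
      ct <- suppressWarnings(as.integer(p[[2]]))
      if (is.na(ct)) stop("bad count field: ", p[[2]], call. = FALSE)
      ct
    } else 1L
  }, 1L)
  target_system(strings, counts)
}

lp_read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readBStringSet(path)
    return(as.character(ss))
  }
  lines <- readLines(path, warn = FALSE)
  headers <- grepl("^>", lines)
  if (!any(headers)) stop("not a FASTA file: ", path, call. = FALSE)
  id <- cumsum(headers)
  seqs <- vapply(split(lines[!headers], id[!headers]),
                 function(x) paste(gsub("\\s", "", x), collapse = ""), "")
  unname(seqs)
}

#' Write a target system to a lines-format file
#' @param target an `lp_target_system`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_targets <- function(target, path) {
  target <- as_target_system(target)
  lines <- ifelse(target$count > 1L,
                  paste0(target$string, "\t", target$count),
                  target$string)
  writeLines(lines, path)
  invisible(path)
}
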