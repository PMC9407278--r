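#' Define a basic set of indivisible building blocks
#'
#' A basic set is the user-declared alphabet from which targets are built.
#' Blocks are non-empty strings; multi-character blocks are allowed (e.g.
#' `"BCD"`), in which case all downstream computations work at the
#' granularity of whole blocks rather than single characters.
#'
#' @param blocks character vector of non-empty, distinct block strings.
#' @return An object of class `lp_basic_set`.
#' @examples
#' basic_set(LETTERS[1:6])
#' basic_set(c("T", "R", "H", "K", "EF", "MU", "BCD"))
#' @export
basic_set <- function(blocks) {
  blocks <- as.character(blocks)
  if (length(blocks) == 0L)
    stop("a basic set needs at least one block", call. = FALSE)
  if (anyNA(blocks) || any(!nzchar(blocks)))
    stop("basic blocks must be non-empty strings", call. = FALSE)
  if (anyDuplicated(blocks))
    stop("basic blocks must be distinct: duplicated ",
         paste(unique(blocks[duplicated(blocks)]), collapse = ", "),
         call. = FALSE)
  blocks <- sort(blocks, method = "radix")
  structure(list(blocks = blocks), class = "lp_basic_set")
}

#' @export
print.lp_basic_set <- function(x, ...) {
  cat("Basic set with", length(x$blocks), "blocks:\n")
  cat(" ", paste(x$blocks, collapse = ", "), "\n")
  invisible(x)
}

#' Default basic set: the single characters observed in the targets
#' @param strings character vector of target strings.
#' @return An `lp_basic_set` of single characters.
#' @export
default_basic_set <- function(strings) {
  chars <- unique(unlist(strsplit(as.character(strings), "", fixed = TRUE)))
  basic_set(chars)
}

is_basic_set <- function(x) inherits(x, "lp_basic_set")

#' Read a basic set from a file, one block per line
#' @param path file path; blank lines and lines starting with `#` are skipped.
#' @return An `lp_basic_set`.
#' @export
read_basic_set <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  basic_set(lines)
}

## ---- tokenization -------------------------------------------------------
## Minimum-token-count segmentation of a string over a basic set, by dynamic
## programming from the right.  Among equal-count segmentations the longest
## matching block is preferred at each position (deterministic canonical
## tokenization).  Returns indices into basic$blocks, or signals an error
## naming the first uncoverable position.

lp_tokenize <- function(string, basic, what = string) {
  stopifnot(is_basic_set(basic))
  if (!nzchar(string)) return(integer(0))
  blocks <- basic$blocks
  # fast path: every block a single character
  if (all(nchar(blocks) == 1L)) {
    chars <- strsplit(string, "", fixed = TRUE)[[1]]
    idx <- match(chars, blocks)
    if (anyNA(idx)) {
      pos <- which(is.na(idx))[1]
      stop(sprintf("target '%s' cannot be tokenized over the basic set: no block covers position %d ('%s')",
                   what, pos, chars[pos]), call. = FALSE)
    }
    return(idx)
  }
  n <- nchar(string)
  ord <- order(-nchar(blocks), blocks, method = "radix")  # longest first
  blocks_o <- blocks[ord]
  len_o <- nchar(blocks_o)
  # best[i] = min tokens for suffix starting at i (1-based), best[n+1] = 0
  best <- rep.int(NA_integer_, n + 1L)
  choice <- rep.int(NA_integer_, n)
  best[n + 1L] <- 0L
  for (i in n:1) {
    for (j in seq_along(blocks_o)) {
      l <- len_o[j]
      if (i + l > n + 1L) next
      if (substr(string, i, i + l - 1L) != blocks_o[j]) next
      nxt <- best[i + l]
      if (is.na(nxt)) next
      cand <- 1L + nxt
      if (is.na(best[i]) || cand < best[i]) {
        best[i] <- cand
        choice[i] <- j
      }
      # blocks_o sorted longest-first: first improvement at this count wins
    }
  }
  if (is.na(best[1])) {
    # first uncoverable position: the furthest start reachable by forward
    # segmentation from which no viable block (one leading to coverage of
    # the rest) departs
    reach <- rep.int(FALSE, n + 1L)
    reach[1] <- TRUE
    for (i in 1:n) {
      if (!reach[i]) next
      for (j in seq_along(blocks_o)) {
        l <- len_o[j]
        if (i + l <= n + 1L && substr(string, i, i + l - 1L) == blocks_o[j])
          reach[i + l] <- TRUE
      }
    }
    pos <- max(which(reach[1:n]))
    stop(sprintf("target '%s' cannot be tokenized over the basic set: no block covers position %d",
                 what, pos), call. = FALSE)
  }
  out <- integer(best[1])
  i <- 1L; k <- 1L
  while (i <= n) {
    j <- choice[i]
    out[k] <- ord[j]
    i <- i + len_o[j]
    k <- k + 1L
  }
  out
}

## minimal number of basic blocks needed to spell `string`; errors when the
## string is not tokenizable
lp_min_tokens <- function(string, basic, what = string) {
  length(lp_tokenize(string, basic, what = what))
}

## TRUE iff tokenizable
lp_tokenizable <- function(string, basic) {
  !inherits(try(lp_tokenize(string, basic), silent = TRUE), "try-error")
}
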