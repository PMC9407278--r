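## Witness segmentation: split `string` into candidate blocks, every block
## from a strictly lower level, such that the maximum constituent level is
## exactly `need_level` (one below the ladderon's own level).  Candidates
## are tried longest-first then lexicographically, left to right, so the
## first witness found is deterministic.
lp_find_segmentation <- function(string, cand_blocks, cand_levels, need_level) {
  ord <- order(-nchar(cand_blocks), cand_blocks, method = "radix")
  cb <- cand_blocks[ord]; cl <- cand_levels[ord]
  n <- nchar(string)
  fail <- new.env(parent = emptyenv())  # (pos, have-flag) -> known dead end
  rec <- function(pos, have) {
    if (pos > n) return(if (have) list() else NULL)
    key <- paste0(pos, ".", have)
    if (!is.null(fail[[key]])) return(NULL)
    for (j in seq_along(cb)) {
      l <- nchar(cb[j])
      if (pos + l - 1L > n) next
      if (substr(string, pos, pos + l - 1L) != cb[j]) next
      res <- rec(pos + l, have || cl[j] == need_level)
      if (!is.null(res)) return(c(list(cb[j]), res))
    }
    fail[[key]] <- TRUE
    NULL
  }
  res <- rec(1L, FALSE)
  if (is.null(res)) NULL else unlist(res)
}

## Decompose each string in `strings` into blocks drawn from a shared pool
## of exact remaining-use counts; the pool must be spent completely.
## Returns a list of segmentations or NULL.
lp_pool_decompose <- function(strings, pool_blocks, pool_counts) {
  ord <- order(-nchar(pool_blocks), pool_blocks, method = "radix")
  pb <- pool_blocks[ord]
  pool <- structure(as.integer(pool_counts[ord]), names = pb)
  segs <- vector("list", length(strings))
  rec_string <- function(si, pos) {
    if (si > length(strings)) return(all(pool == 0L))
    s <- strings[si]
    if (pos > nchar(s)) return(rec_string(si + 1L, 1L))
    for (b in pb) {
      if (pool[[b]] <= 0L) next
      l <- nchar(b)
      if (pos + l - 1L > nchar(s)) next
      if (substr(s, pos, pos + l - 1L) != b) next
      pool[[b]] <<- pool[[b]] - 1L
      segs[[si]] <<- c(segs[[si]], b)
      if (rec_string(si, pos + l)) return(TRUE)
      pool[[b]] <<- pool[[b]] + 1L
      segs[[si]] <<- segs[[si]][-length(segs[[si]])]
    }
    FALSE
  }
  if (rec_string(1L, 1L)) segs else NULL
}

#' Validate a ladderpath and produce a witness generation path
#'
#' A ladderpath is valid when (a) every non-basic ladderon admits a
#' segmentation into blocks of strictly lower levels whose maximum level is
#' one below its own, (b) per-unit conservation holds, and (c) all
#' multiplicities are positive and blocks are unique across levels.  On
#' success one witness generation path realizing the ladderpath is
#' constructed: each non-basic ladderon is merged once from its witness
#' segmentation, target instances are assembled from the remaining reuse
#' budget, and all instances are taken out.
#'
#' @param lp a `ladderpath` object.
#' @return An object of class `lp_validation`: a list with elements `valid`
#'   (logical), `reason` (`NULL` or the first violated invariant),
#'   `segmentations` (named list of witness segmentations for the non-basic
#'   ladderons) and `witness` (an [generation_path()], or `NULL`).
#' @export
validate_ladderpath <- function(lp) {
  stopifnot(inherits(lp, "ladderpath"))
  bad <- function(reason) structure(list(valid = FALSE, reason = reason,
                                         segmentations = NULL, witness = NULL),
                                    class = "lp_validation")
  ld <- lp$ladderons
  if (nrow(ld)) {
    if (any(ld$multiplicity < 1L))
      return(bad(paste0("non-positive multiplicity for block ",
                        ld$block[ld$multiplicity < 1L][1])))
    if (anyDuplicated(ld$block))
      return(bad(paste0("block listed more than once: ",
                        ld$block[duplicated(ld$block)][1])))
    if (any(ld$basic & ld$level != 1L))
      return(bad(paste0("basic block not at level 1: ",
                        ld$block[ld$basic & ld$level != 1L][1])))
    if (any(!ld$basic & ld$level < 2L))
      return(bad(paste0("non-basic block at level 1: ",
                        ld$block[!ld$basic & ld$level < 2L][1])))
  }

  # (a) witness segmentations, bottom-up
  segs <- list()
  nb <- which(!ld$basic)
  nb <- nb[order(ld$level[nb], ld$block[nb], method = "radix")]
  for (i in nb) {
    lower <- ld$level < ld$level[i]
    cand_blocks <- ld$block[lower]
    cand_levels <- ld$level[lower]
    extra <- setdiff(lp$basic$blocks, cand_blocks)
    cand_blocks <- c(cand_blocks, extra)
    cand_levels <- c(cand_levels, rep.int(1L, length(extra)))
    seg <- lp_find_segmentation(ld$block[i], cand_blocks, cand_levels,
                                need_level = ld$level[i] - 1L)
    if (is.null(seg))
      return(bad(paste0("no witness segmentation for ladderon ", ld$block[i],
                        " at level ", ld$level[i])))
    segs[[ld$block[i]]] <- seg
  }

  # (b) conservation
  cons <- conservation_check(lp)
  if (!all(cons$ok))
    return(bad(paste0("conservation fails for unit(s): ",
                      paste(cons$unit[!cons$ok], collapse = ", "))))

  # witness path: remaining reuse budget after generating each non-basic
  # ladderon once and taking out all target instances
  blocks <- ld$block
  uses <- structure(rep.int(0L, length(blocks)), names = blocks)
  for (seg in segs)
    for (b in seg) if (b %in% blocks) uses[b] <- uses[b] + 1L
  members_in <- lp$target$string %in% blocks
  for (i in which(members_in))
    uses[lp$target$string[i]] <- uses[lp$target$string[i]] + lp$target$count[i]
  created <- ifelse(ld$basic, 0L, 1L)
  pool <- ld$multiplicity + created - uses
  witness <- NULL
  if (all(pool >= 0L)) {
    rest <- lp$target$string[!members_in]
    dec <- lp_pool_decompose(rest, blocks, pool)
    if (!is.null(dec)) {
      ops <- list()
      for (i in nb) ops <- c(ops, list(op_merge(segs[[ld$block[i]]],
                                               ld$block[i])))
      for (k in seq_along(rest))
        ops <- c(ops, list(op_merge(dec[[k]], rest[k])))
      ops <- c(ops, list(op_takeout(rep(lp$target$string, lp$target$count))))
      witness <- generation_path(ops, lp$basic, lp$target)
    }
  }
  structure(list(valid = TRUE, reason = NULL, segmentations = segs,
                 witness = witness),
            class = "lp_validation")
}

#' @export
print.lp_validation <- function(x, ...) {
  if (x$valid) {
    cat("Valid ladderpath\n")
    if (!is.null(x$witness))
      cat("  witness path with", length(x$witness$ops), "operation(s)\n")
  } else {
    cat("Invalid ladderpath:", x$reason, "\n")
  }
  invisible(x)
}
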