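#' Brute-force reference for shortest ladderpaths of tiny targets
#'
#' Exhaustively enumerates every candidate ladderon set (all subsets of the
#' substrings with at least two disjoint occurrences across the target
#' members) and every combination of minimal segmentations, and returns
#' the true minimum ladderpath length together with the number of distinct
#' canonical ladderpaths attaining it.  Deliberately naive and entirely
#' separate from the search engine, so agreement between the two is
#' evidence rather than tautology.  Only single-character basic sets are
#' supported and hard limits on input size are enforced.
#'
#' @param target a [target_system()] or character vector.
#' @param basic a [basic_set()] of single characters; defaults to the
#'   characters observed.
#' @param max_total_length refuse inputs whose distinct members exceed this
#'   many letters in total (default 9).
#' @param max_alphabet refuse inputs over more than this many distinct
#'   letters (default 4).
#' @return A list with `min_length` (lifts) and `n_shortest` (number of
#'   distinct canonical ladderpaths of minimum length).
#' @export
lp_oracle <- function(target, basic = NULL, max_total_length = 9L,
                      max_alphabet = 4L) {
  target <- as_target_system(target)
  if (nrow(target) == 0L) return(list(min_length = 0L, n_shortest = 1L))
  if (is.null(basic)) basic <- default_basic_set(target$string)
  if (any(nchar(basic$blocks) != 1L))
    stop("the oracle handles single-character basic sets only",
         call. = FALSE)
  if (sum(nchar(target$string)) > max_total_length)
    stop("oracle limit exceeded: total length ", sum(nchar(target$string)),
         " > ", max_total_length, call. = FALSE)
  if (length(basic$blocks) > max_alphabet)
    stop("oracle limit exceeded: alphabet size ", length(basic$blocks),
         " > ", max_alphabet, call. = FALSE)
  members <- target$string
  instances <- sum(target$count)

  # candidate ladderons: substrings (length >= 2) with >= 2 disjoint
  # occurrences somewhere across the distinct members
  subs <- character(0)
  for (s in members)
    for (l in 2:max(2L, nchar(s)))
      for (i in seq_len(max(0L, nchar(s) - l + 1L)))
        subs <- c(subs, substr(s, i, i + l - 1L))
  subs <- unique(subs[nchar(subs) >= 2L])
  count_disjoint <- function(b) {
    tot <- 0L
    for (s in members) {
      pos <- 1L
      while (pos + nchar(b) - 1L <= nchar(s)) {
        hit <- regexpr(b, substr(s, pos, nchar(s)), fixed = TRUE)
        if (hit < 0L) break
        tot <- tot + 1L
        pos <- pos + hit - 1L + nchar(b)
      }
    }
    tot
  }
  cands <- subs[vapply(subs, count_disjoint, 0L) >= 2L]

  # all minimal segmentations of `s` over `blocks`, by plain recursion
  all_minsegs <- function(s, blocks) {
    if (!nzchar(s)) return(list(character(0)))
    best <- Inf; acc <- list()
    for (b in blocks) {
      if (nchar(b) > nchar(s)) next
      if (substr(s, 1L, nchar(b)) != b) next
      rest <- all_minsegs(substr(s, nchar(b) + 1L, nchar(s)), blocks)
      for (r in rest) {
        n <- 1L + length(r)
        if (n < best) { best <- n; acc <- list() }
        if (n == best) acc[[length(acc) + 1L]] <- c(b, r)
      }
    }
    acc
  }

  best_cost <- Inf
  best_poms <- character(0)
  n_c <- length(cands)
  for (mask in 0:(2^n_c - 1L)) {
    L <- cands[bitwAnd(mask, bitwShiftL(1L, seq_len(n_c) - 1L)) > 0L]
    # segmentations: each ladderon over strictly shorter blocks, each
    # member over any blocks (itself included when it is a ladderon)
    need <- list()   # block -> list of minimal segmentations
    cost <- 0L
    ok <- TRUE
    for (b in L) {
      blocks <- c(basic$blocks, L[nchar(L) < nchar(b)])
      segs <- all_minsegs(b, blocks)
      need[[b]] <- segs
      cost <- cost + length(segs[[1]]) - 1L
    }
    mem_prod <- list()
    for (s in members) {
      if (s %in% L || s %in% basic$blocks) next  # production covered / basic
      blocks <- c(basic$blocks, L[nchar(L) <= nchar(s)])
      segs <- all_minsegs(s, blocks)
      # a member segmented as just itself means it is a ladderon; excluded
      segs <- Filter(function(g) !(length(g) == 1L && g == s), segs)
      if (!length(segs)) { ok <- FALSE; break }
      mem_prod[[s]] <- segs
      cost <- cost + length(segs[[1]]) - 1L
    }
    if (!ok) next
    cost <- cost + instances
    if (cost > best_cost) next
    # materialize every ladderpath from the segmentation combinations
    owners <- c(L, names(mem_prod))
    segsets <- c(need, mem_prod)[owners]
    combos <- list(integer(0))
    for (k in seq_along(owners)) {
      combos <- unlist(lapply(combos, function(cb)
        lapply(seq_along(segsets[[k]]), function(x) c(cb, x))),
        recursive = FALSE)
    }
    for (cb in combos) {
      prods <- lapply(seq_along(owners), function(k) segsets[[k]][[cb[k]]])
      names(prods) <- owners
      pom <- lp_oracle_pom(prods, basic, target)
      if (is.null(pom)) next
      if (cost < best_cost) { best_cost <- cost; best_poms <- character(0) }
      best_poms <- unique(c(best_poms, pom))
    }
  }
  list(min_length = as.integer(best_cost), n_shortest = length(best_poms))
}

## net-multiplicity bookkeeping for one grammar; returns the canonical
## notation string of the resulting ladderpath
lp_oracle_pom <- function(prods, basic, target) {
  blocks <- unique(c(basic$blocks, names(prods), target$string))
  uses <- structure(rep.int(0L, length(blocks)), names = blocks)
  for (p in prods) for (b in p) uses[b] <- uses[b] + 1L
  takeout <- structure(rep.int(0L, length(blocks)), names = blocks)
  for (i in seq_len(nrow(target)))
    takeout[target$string[i]] <- takeout[target$string[i]] +
      target$count[i]
  created <- as.integer(blocks %in% names(prods))
  net <- created - uses - takeout
  level <- structure(rep.int(1L, length(blocks)), names = blocks)
  for (b in blocks[order(nchar(blocks))]) {
    p <- prods[[b]]
    if (!is.null(p)) level[b] <- 1L + max(level[p])
  }
  keep <- net != 0L
  if (!any(keep)) return("{}")
  df <- data.frame(block = blocks[keep], multiplicity = abs(net[keep]),
                   level = level[keep], stringsAsFactors = FALSE)
  df <- df[order(df$level, df$block, method = "radix"), , drop = FALSE]
  items <- paste0(df$block, ifelse(df$multiplicity > 1L,
                                   sprintf("(%d)", df$multiplicity), ""))
  paste0("{", paste(vapply(split(items, df$level), paste, "",
                           collapse = ", "), collapse = " // "), "}")
}
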