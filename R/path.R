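#' Generation-operations and generation paths
#'
#' A generation path is the procedural view that a ladderpath abstracts: an
#' ordered sequence of generation-operations on a partially ordered multiset
#' of blocks.  A *merge* takes `n >= 2` blocks (multiplicities decrement,
#' negative transients are allowed) and puts their concatenation back one
#' level above the highest constituent, costing `n - 1` lifts.  The final
#' *take-out* removes the finished target instances at 1 lift each.
#'
#' @param inputs character vector (length >= 2) of blocks to concatenate,
#'   in order.
#' @param output the merged block; must equal `paste(inputs, collapse="")`.
#' @return An operation object for [generation_path()].
#' @examples
#' op_merge(c("C", "D"), "CD")
#' op_takeout("ABCDBCDBCDCDEFEF")
#' @export
op_merge <- function(inputs, output = paste(inputs, collapse = "")) {
  inputs <- as.character(inputs)
  if (length(inputs) < 2L)
    stop("a merge needs at least two input blocks", call. = FALSE)
  if (!identical(paste(inputs, collapse = ""), as.character(output)))
    stop("merge output must be the concatenation of its inputs", call. = FALSE)
  structure(list(kind = "merge", inputs = inputs,
                 output = as.character(output)), class = "lp_op")
}

#' @rdname op_merge
#' @param blocks character vector of target instances to take out (repeats
#'   allowed, one lift each).
#' @export
op_takeout <- function(blocks) {
  blocks <- as.character(blocks)
  if (length(blocks) == 0L)
    stop("take-out needs at least one block", call. = FALSE)
  structure(list(kind = "takeout", inputs = blocks, output = NULL),
            class = "lp_op")
}

#' Assemble a generation path
#'
#' @param ops list of operations from [op_merge()] / [op_takeout()].
#' @param basic a [basic_set()].
#' @param target the [target_system()] the path is meant to produce.
#' @return An object of class `lp_generation_path`.
#' @export
generation_path <- function(ops, basic, target) {
  stopifnot(is_basic_set(basic))
  target <- as_target_system(target)
  if (!all(vapply(ops, inherits, TRUE, "lp_op")))
    stop("ops must be built with op_merge()/op_takeout()", call. = FALSE)
  structure(list(ops = ops, basic = basic, target = target),
            class = "lp_generation_path")
}

#' @export
print.lp_generation_path <- function(x, ...) {
  cat("Generation path with", length(x$ops), "operation(s)\n")
  for (op in x$ops) {
    if (op$kind == "merge")
      cat(sprintf("  %s = %s\n", paste(op$inputs, collapse = " + "),
                  op$output))
    else
      cat(sprintf("  take out %s\n", paste(op$inputs, collapse = ", ")))
  }
  invisible(x)
}

#' Replay a generation path and measure its length
#'
#' Replays the multiset bookkeeping: merges decrement their inputs (negative
#' transients allowed), add the output one level above the highest
#' constituent, and cost `n - 1` lifts; take-outs cost 1 lift per instance
#' and, like merges, may drive a count negative in passing (several
#' instances of a once-generated block can be removed, reflecting reuse).
#' A merge whose output is already a known
#' block is rejected (newly generated blocks must not be present in the
#' set), as is a take-out of a block that was never generated and is not
#' basic.
#'
#' @param path an [generation_path()].
#' @return A list with elements `final` (data frame `block`, `count`,
#'   `level` of the signed multiset after all operations), `length` (total
#'   lifts), `op_costs` (lifts per operation) and `taken_out` (character
#'   vector of removed instances).
#' @export
simulate_path <- function(path) {
  stopifnot(inherits(path, "lp_generation_path"))
  counts <- structure(rep.int(0L, length(path$basic$blocks)),
                      names = path$basic$blocks)
  levels <- structure(rep.int(1L, length(path$basic$blocks)),
                      names = path$basic$blocks)
  op_costs <- integer(length(path$ops))
  taken_out <- character(0)
  for (k in seq_along(path$ops)) {
    op <- path$ops[[k]]
    if (op$kind == "merge") {
      unknown <- setdiff(op$inputs, names(counts))
      if (length(unknown))
        stop("merge input not present in the multiset: ",
             paste(unique(unknown), collapse = ", "), call. = FALSE)
      if (op$output %in% names(counts))
        stop(sprintf("operation %d: the newly-generated block '%s' must not be present in the set",
                     k, op$output), call. = FALSE)
      for (b in op$inputs) counts[b] <- counts[b] - 1L
      counts[op$output] <- 1L
      levels[op$output] <- 1L + max(levels[op$inputs])
      op_costs[k] <- length(op$inputs) - 1L
    } else {
      for (b in op$inputs) {
        if (!b %in% names(counts))
          stop(sprintf("operation %d: cannot take out '%s' (never generated and not basic)",
                       k, b), call. = FALSE)
        counts[b] <- counts[b] - 1L
      }
      taken_out <- c(taken_out, op$inputs)
      op_costs[k] <- length(op$inputs)
    }
  }
  final <- data.frame(block = names(counts), count = as.integer(counts),
                      level = as.integer(levels[names(counts)]),
                      stringsAsFactors = FALSE, row.names = NULL)
  list(final = final, length = sum(op_costs), op_costs = op_costs,
       taken_out = taken_out)
}

#' Distill a generation path into its ladderpath
#'
#' Replays the path, checks that every target instance has been taken out,
#' deletes all blocks with zero final multiplicity and takes absolute values
#' of the rest, preserving the partial order.  The length of the resulting
#' ladderpath always equals the replayed path length.
#'
#' @inheritParams simulate_path
#' @return A `ladderpath` object.
#' @export
path_to_ladderpath <- function(path) {
  sim <- simulate_path(path)
  need <- path$target
  got <- table(sim$taken_out)
  for (i in seq_len(nrow(need))) {
    s <- need$string[i]
    if (is.na(got[s]) || got[s] != need$count[i])
      stop(sprintf("path does not take out target '%s' exactly %d time(s)",
                   s, need$count[i]), call. = FALSE)
  }
  if (sum(got) != sum(need$count))
    stop("path takes out blocks that are not target instances", call. = FALSE)
  keep <- sim$final$count != 0L
  ladderons <- data.frame(block = sim$final$block[keep],
                          multiplicity = abs(sim$final$count[keep]),
                          level = sim$final$level[keep],
                          stringsAsFactors = FALSE)
  new_ladderpath(ladderons, path$basic, path$target, mode = "path")
}
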