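## Internal constructor for the central S3 class.
##
## A ladderpath is a partially ordered multiset of ladderons: a data frame
## with columns block / multiplicity / level (basic blocks at level 1),
## bound to the basic set and the target system it decomposes.  `lambda`
## is the length of *this* ladderpath (Eq.-style closed form); for search
## results it is the minimum found and `optimal` records whether the state
## space was exhausted.
new_ladderpath <- function(ladderons, basic, target,
                           mode = "given", optimal = NA, call = NULL) {
  stopifnot(is_basic_set(basic))
  target <- as_target_system(target)
  if (nrow(ladderons) > 0L) {
    ladderons$block <- as.character(ladderons$block)
    ladderons$multiplicity <- as.integer(ladderons$multiplicity)
    ladderons$level <- as.integer(ladderons$level)
    ladderons$basic <- ladderons$block %in% basic$blocks
    ord <- order(ladderons$level, ladderons$block, method = "radix")
    ladderons <- ladderons[ord, c("block", "multiplicity", "level", "basic"),
                           drop = FALSE]
    rownames(ladderons) <- NULL
  } else {
    ladderons <- data.frame(block = character(0), multiplicity = integer(0),
                            level = integer(0), basic = logical(0),
                            stringsAsFactors = FALSE)
  }
  lp <- structure(list(ladderons = ladderons, basic = basic, target = target,
                       S = NA_integer_, lambda = NA_integer_,
                       omega = NA_integer_, optimal = optimal, mode = mode,
                       call = call),
                  class = "ladderpath")
  lp$S <- size_index(target, basic)
  lp$lambda <- ladderpath_length(lp)
  lp$omega <- lp$S - lp$lambda
  lp
}

#' @export
print.ladderpath <- function(x, ...) {
  n_inst <- lp_n_instances(x$target)
  cat(sprintf("Ladderpath of %d target instance(s), %d distinct string(s)\n",
              n_inst, nrow(x$target)))
  cat(" ", serialize_pom(x), "\n")
  cat(sprintf("  S = %d, lambda = %d, omega = %d lifts\n",
              x$S, x$lambda, x$omega))
  if (identical(x$mode, "exact") || identical(x$mode, "heuristic")) {
    cat(sprintf("  search: %s%s\n", x$mode,
                if (isTRUE(x$optimal)) " (proven shortest)"
                else if (isFALSE(x$optimal)) " (shortest not guaranteed)"
                else ""))
  }
  invisible(x)
}

#' @export
summary.ladderpath <- function(object, ...) {
  sizes <- if (nrow(object$ladderons)) lp_block_sizes(object) else integer(0)
  ladderons <- object$ladderons
  ladderons$size <- as.integer(sizes)
  ladderons$saved <- ifelse(ladderons$basic, 0L,
                            ladderons$multiplicity * (ladderons$size - 1L))
  structure(list(ladderons = ladderons, target = object$target,
                 basic = object$basic, S = object$S, lambda = object$lambda,
                 omega = object$omega, mode = object$mode,
                 optimal = object$optimal, pom = serialize_pom(object)),
            class = "summary.ladderpath")
}

#' @export
print.summary.ladderpath <- function(x, ...) {
  cat("Ladderpath summary\n")
  cat("  notation:", x$pom, "\n")
  cat(sprintf("  size-index S      = %3d lifts\n", x$S))
  cat(sprintf("  ladderpath-index  = %3d lifts (lambda)\n", x$lambda))
  cat(sprintf("  order-index       = %3d lifts (omega)\n", x$omega))
  nb <- x$ladderons[!x$ladderons$basic, , drop = FALSE]
  if (nrow(nb)) {
    cat("  non-basic ladderons:\n")
    for (i in seq_len(nrow(nb)))
      cat(sprintf("    %-12s level %d, multiplicity %d, saves %d lift(s)\n",
                  nb$block[i], nb$level[i], nb$multiplicity[i], nb$saved[i]))
  } else {
    cat("  trivial (no non-basic ladderons)\n")
  }
  invisible(x)
}

#' @export
coef.ladderpath <- function(object, ...) {
  c(S = object$S, lambda = object$lambda, omega = object$omega)
}

#' Lay out and draw a laddergraph with base graphics
#'
#' Nodes are the blocks of the ladderpath grouped by level (basic blocks at
#' the bottom), plus the target strings on top; edges are the constituent
#' relations of the witness segmentations after transitive reduction, with
#' edges incident to basic blocks dimmed.
#'
#' @param x a `ladderpath` object.
#' @param ... passed to [graphics::plot.default()].
#' @return `x`, invisibly.
#' @export
plot.ladderpath <- function(x, ...) {
  g <- lp_laddergraph(x)
  nodes <- g$nodes; edges <- g$edges
  lv <- split(seq_len(nrow(nodes)), nodes$level)
  xs <- numeric(nrow(nodes)); ys <- numeric(nrow(nodes))
  for (l in names(lv)) {
    idx <- lv[[l]]
    xs[idx] <- seq_along(idx) / (length(idx) + 1)
    ys[idx] <- as.numeric(l)
  }
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0.5, max(ys) + 0.5),
                 axes = FALSE, xlab = "", ylab = "level", ...)
  graphics::axis(2, at = sort(unique(ys)),
                 labels = sort(unique(nodes$level)), las = 1)
  if (nrow(edges)) {
    fi <- match(edges$from, nodes$id); ti <- match(edges$to, nodes$id)
    graphics::segments(xs[fi], ys[fi] + 0.08, xs[ti], ys[ti] - 0.12,
                       col = ifelse(edges$dim, "grey70", "grey20"))
  }
  graphics::text(xs, ys, labels = nodes$label,
                 col = ifelse(nodes$target, "grey40", "black"), font = 2)
  invisible(x)
}
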