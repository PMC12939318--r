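## Dependency-matrix analysis.
##
## The effect of node A on node B is classified from the elementary
## (node-distinct) directed paths A -> B, a path's sign being the
## product of its edge signs, and for A = B from the elementary
## circuits through A. A negative feedback loop is a negative
## elementary circuit; it is "present in" a set of paths iff it shares
## at least one node with at least one path of the set. Classes:
##   no paths                                    -> NO_EFFECT
##   both signs present                          -> AMBIVALENT
##   only negative, some path touches a neg loop -> WEAK_INHIBITOR
##   only negative, none touched                 -> STRONG_INHIBITOR
##   only positive, some path touches a neg loop -> WEAK_ACTIVATOR
##   only positive, none touched                 -> STRONG_ACTIVATOR

#' Dependency class levels
#'
#' The six dependency classes, in reporting order, and their
#' two/three-letter abbreviations used in TSV output.
#' @export
dependency_classes <- function() {
  c("NO_EFFECT", "AMBIVALENT", "WEAK_INHIBITOR", "WEAK_ACTIVATOR",
    "STRONG_INHIBITOR", "STRONG_ACTIVATOR")
}

.dep_abbrev <- c(NO_EFFECT = "NE", AMBIVALENT = "AMB", WEAK_INHIBITOR = "WI",
                 WEAK_ACTIVATOR = "WA", STRONG_INHIBITOR = "SI",
                 STRONG_ACTIVATOR = "SA")

## integer adjacency: list over node ids, each a 2-column matrix (to, sign)
.adjacency <- function(net) {
  idx <- setNames(seq_along(net$nodes), net$nodes)
  from <- idx[net$edges$source]
  to <- idx[net$edges$target]
  sgn <- net$edges$sign
  lapply(seq_along(net$nodes), function(v) {
    sel <- which(from == v)
    cbind(to = to[sel], sign = sgn[sel])
  })
}

## Nodes lying on at least one negative elementary circuit.
## Circuits are enumerated once each by a Johnson-style restriction:
## a DFS rooted at s only visits nodes with id >= s, so every circuit
## is found exactly from its minimum-id node.
.neg_loop_nodes <- function(adj, n) {
  on_neg <- rep(FALSE, n)
  for (s in seq_len(n)) {
    visited <- rep(FALSE, n)
    visited[s] <- TRUE
    path <- integer(0)
    dfs <- function(v, sgn) {
      nb <- adj[[v]]
      for (k in seq_len(nrow(nb))) {
        w <- nb[k, 1L]
        ns <- sgn * nb[k, 2L]
        if (w == s) {
          if (ns == -1L) on_neg[c(s, path)] <<- TRUE
        } else if (w >= s && !visited[w]) {
          visited[w] <<- TRUE
          path[length(path) + 1L] <<- w
          dfs(w, ns)
          path <<- path[-length(path)]
          visited[w] <<- FALSE
        }
      }
      invisible(NULL)
    }
    if (nrow(adj[[s]])) dfs(s, 1L)
  }
  on_neg
}

## Classify one ordered pair by pruned DFS over elementary paths
## (elementary circuits when a == b). Stops as soon as both signs have
## been seen (AMBIVALENT is then decided regardless of loop contact).
.classify_pair <- function(adj, on_neg, a, b, n) {
  found <- c(pos = FALSE, neg = FALSE, posT = FALSE, negT = FALSE)
  visited <- rep(FALSE, n)
  visited[a] <- TRUE
  dfs <- function(v, sgn, touched) {
    nb <- adj[[v]]
    for (k in seq_len(nrow(nb))) {
      w <- nb[k, 1L]
      ns <- sgn * nb[k, 2L]
      if (w == b) {
        tch <- touched || on_neg[b]
        if (ns == 1L) {
          found["pos"] <<- TRUE
          if (tch) found["posT"] <<- TRUE
        } else {
          found["neg"] <<- TRUE
          if (tch) found["negT"] <<- TRUE
        }
        if (found[["pos"]] && found[["neg"]]) return(TRUE)
      }
      if (w != b && !visited[w]) {
        visited[w] <<- TRUE
        done <- dfs(w, ns, touched || on_neg[w])
        visited[w] <<- FALSE
        if (done) return(TRUE)
      }
    }
    FALSE
  }
  if (nrow(adj[[a]])) dfs(a, 1L, on_neg[a])
  .classify_from_flags(found)
}

.classify_from_flags <- function(found) {
  if (!found[["pos"]] && !found[["neg"]]) return("NO_EFFECT")
  if (found[["pos"]] && found[["neg"]]) return("AMBIVALENT")
  if (found[["neg"]]) {
    if (found[["negT"]]) "WEAK_INHIBITOR" else "STRONG_INHIBITOR"
  } else {
    if (found[["posT"]]) "WEAK_ACTIVATOR" else "STRONG_ACTIVATOR"
  }
}

#' Compute the dependency matrix of a signed network
#'
#' Classifies the net qualitative effect of every node on every node
#' (including each node on itself) into one of six classes; see
#' [dependency_classes()]. Row = acting (source) node, column =
#' affected (target) node: entry `(A, B)` is the effect *of* A *on* B
#' via directed paths from A to B.
#'
#' Paths are elementary (no repeated nodes); diagonal entries use the
#' elementary circuits through the node, so a node can depend on
#' itself only via a feedback loop. "Weak" versus "strong" is decided
#' by whether a negative elementary circuit shares a node with at
#' least one path of the classified sign.
#'
#' The implementation is a depth-first enumeration of elementary paths
#' with early termination (a pair is ambivalent as soon as one path of
#' each sign is seen); [dependency_matrix_bruteforce()] is an
#' independent literal-enumeration oracle for cross-checking.
#'
#' @param net a [signed_network()].
#' @return An object of class `dependency_matrix`: a character matrix
#'   (rows = acting node, columns = affected node) over
#'   [dependency_classes()].
#' @examples
#' net <- signed_network(data.frame(
#'   source = c("A", "B", "C"), target = c("B", "C", "B"),
#'   sign = c(1, 1, -1)))
#' dependency_matrix(net)
#' @export
dependency_matrix <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  n <- length(net$nodes)
  adj <- .adjacency(net)
  on_neg <- .neg_loop_nodes(adj, n)
  m <- matrix("NO_EFFECT", n, n, dimnames = list(net$nodes, net$nodes))
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      m[a, b] <- .classify_pair(adj, on_neg, a, b, n)
    }
  }
  structure(m, class = c("dependency_matrix", class(m)))
}

## ---- brute-force oracle (igraph route) -------------------------------

## All achievable sign products along a vertex path, given possibly
## parallel opposite-sign edges between consecutive vertices.
.path_signs <- function(vpath, sign_set) {
  signs <- 1L
  for (i in seq_len(length(vpath) - 1L)) {
    s <- sign_set[[paste(vpath[i], vpath[i + 1L])]]
    signs <- unique(as.integer(outer(signs, s)))
  }
  signs
}

## Enumerate all elementary paths a -> b (circuits through a when
## a == b) as a list of (nodes, signs achievable).
.enumerate_paths_igraph <- function(g, sign_set, a, b) {
  out <- list()
  if (a != b) {
    vps <- igraph::all_simple_paths(g, from = a, to = b, mode = "out")
    for (vp in vps) {
      ids <- as.integer(vp)
      out[[length(out) + 1L]] <- list(nodes = ids,
                                      signs = .path_signs(ids, sign_set))
    }
  } else {
    key_self <- paste(a, a)
    if (!is.null(sign_set[[key_self]])) {
      out[[length(out) + 1L]] <- list(nodes = a, signs = sign_set[[key_self]])
    }
    preds <- as.integer(igraph::neighbors(g, a, mode = "in"))
    for (u in setdiff(unique(preds), a)) {
      vps <- igraph::all_simple_paths(g, from = a, to = u, mode = "out")
      close_signs <- sign_set[[paste(u, a)]]
      for (vp in vps) {
        ids <- as.integer(vp)
        open_signs <- .path_signs(ids, sign_set)
        signs <- unique(as.integer(outer(open_signs, close_signs)))
        out[[length(out) + 1L]] <- list(nodes = ids, signs = signs)
      }
    }
  }
  out
}

#' Brute-force dependency matrix (verification oracle)
#'
#' Same contract as [dependency_matrix()], implemented independently
#' by literal enumeration of all elementary paths and all elementary
#' circuits (via `igraph` simple-path enumeration, with parallel
#' opposite-sign edges expanded into all achievable path signs).
#' Intended as a correctness oracle on small networks; guarded against
#' combinatorial explosion.
#'
#' @param net a [signed_network()].
#' @param max_nodes refuse networks larger than this (default 12).
#' @return A `dependency_matrix`.
#' @export
dependency_matrix_bruteforce <- function(net, max_nodes = 12L) {
  stopifnot(inherits(net, "signed_network"))
  n <- length(net$nodes)
  if (n > max_nodes) {
    stop("network has ", n, " nodes (> max_nodes = ", max_nodes,
         "); use dependency_matrix() for large networks")
  }
  idx <- setNames(seq_len(n), net$nodes)
  g <- igraph::make_empty_graph(n = n, directed = TRUE)
  if (nrow(net$edges)) {
    ## one igraph edge per distinct (source, target); signs kept aside
    uniq <- unique(net$edges[, c("source", "target")])
    g <- igraph::add_edges(g, rbind(idx[uniq$source], idx[uniq$target]))
  }
  sign_set <- list()
  for (i in seq_len(nrow(net$edges))) {
    key <- paste(idx[[net$edges$source[i]]], idx[[net$edges$target[i]]])
    sign_set[[key]] <- unique(c(sign_set[[key]], net$edges$sign[i]))
  }
  ## nodes on negative elementary circuits, from complete circuit lists
  on_neg <- rep(FALSE, n)
  for (v in seq_len(n)) {
    for (circ in .enumerate_paths_igraph(g, sign_set, v, v)) {
      if (-1L %in% circ$signs) on_neg[circ$nodes] <- TRUE
    }
  }
  m <- matrix("NO_EFFECT", n, n, dimnames = list(net$nodes, net$nodes))
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      paths <- .enumerate_paths_igraph(g, sign_set, a, b)
      found <- c(pos = FALSE, neg = FALSE, posT = FALSE, negT = FALSE)
      for (p in paths) {
        touched <- any(on_neg[p$nodes])
        if (1L %in% p$signs) {
          found["pos"] <- TRUE
          if (touched) found["posT"] <- TRUE
        }
        if (-1L %in% p$signs) {
          found["neg"] <- TRUE
          if (touched) found["negT"] <- TRUE
        }
      }
      m[a, b] <- .classify_from_flags(found)
    }
  }
  structure(m, class = c("dependency_matrix", class(m)))
}

#' @export
print.dependency_matrix <- function(x, ...) {
  cat(sprintf("dependency_matrix: %d x %d (%d dependencies)\n",
              nrow(x), ncol(x), length(x)))
  ab <- matrix(.dep_abbrev[x], nrow(x), dimnames = dimnames(x))
  print(ab, quote = FALSE)
  invisible(x)
}

#' Count dependencies per class
#'
#' @param dm a [dependency_matrix()].
#' @return Named integer vector over [dependency_classes()] (summing
#'   to `nrow(dm)^2`), with a `total` attribute-free sum available via
#'   `sum()`.
#' @export
class_counts <- function(dm) {
  stopifnot(inherits(dm, "dependency_matrix"))
  tab <- table(factor(unclass(dm), levels = dependency_classes()))
  setNames(as.integer(tab), dependency_classes())
}

#' Dependency changes between two matrices
#'
#' Compares a base dependency matrix with a comparative one (typically
#' wild-type versus a structural knockout, whose matrix lacks the
#' deleted node's row and column). The comparison is restricted to the
#' common node set, so for a single knockout from an n-node network the
#' change counts are over (n-1) x (n-1) ordered pairs.
#'
#' @param dm_before,dm_after [dependency_matrix()] objects;
#'   `dm_after`'s node set must be a subset of `dm_before`'s.
#' @return list of class `dependency_delta` with:
#'   `pairs` (data.frame `source`, `target`, `before`, `after` over all
#'   common ordered pairs), `n_changed`, `transitions` (6 x 6 count
#'   matrix, rows = before class, columns = after class), and
#'   `strong_changes` (the changed pairs whose after-class is
#'   `STRONG_ACTIVATOR` or `STRONG_INHIBITOR`).
#' @export
dm_delta <- function(dm_before, dm_after) {
  stopifnot(inherits(dm_before, "dependency_matrix"),
            inherits(dm_after, "dependency_matrix"))
  nodes_b <- rownames(dm_before)
  nodes_a <- rownames(dm_after)
  extra <- setdiff(nodes_a, nodes_b)
  if (length(extra)) {
    stop("after-matrix has node(s) absent from before-matrix: ",
         paste(extra, collapse = ", "))
  }
  common <- intersect(nodes_b, nodes_a)
  before <- unclass(dm_before)[common, common, drop = FALSE]
  after <- unclass(dm_after)[common, common, drop = FALSE]
  pairs <- data.frame(
    source = rep(common, times = length(common)),
    target = rep(common, each = length(common)),
    before = as.vector(before[, , drop = TRUE]),
    after = as.vector(after[, , drop = TRUE]))
  ## as.vector on a matrix is column-major: source varies fastest
  changed <- pairs$before != pairs$after
  lev <- dependency_classes()
  transitions <- table(factor(pairs$before, levels = lev),
                       factor(pairs$after, levels = lev))
  transitions <- matrix(as.integer(transitions), 6L, 6L,
                        dimnames = list(before = lev, after = lev))
  strong <- pairs[changed & pairs$after %in%
                    c("STRONG_ACTIVATOR", "STRONG_INHIBITOR"), , drop = FALSE]
  rownames(strong) <- NULL
  structure(list(pairs = pairs, n_changed = sum(changed),
                 transitions = transitions, strong_changes = strong),
            class = "dependency_delta")
}

#' @export
print.dependency_delta <- function(x, ...) {
  cat(sprintf("dependency_delta: %d of %d dependencies changed; %d changes to strong classes\n",
              x$n_changed, nrow(x$pairs), nrow(x$strong_changes)))
  invisible(x)
}

#' In-silico knockout scenario report
#'
#' For each node in `nodes_to_delete`, deletes the node
#' ([knockout()]), recomputes the dependency matrix on the reduced
#' network, and reports its class counts together with the dependency
#' changes relative to the full model ([dm_delta()]).
#'
#' @param net a [signed_network()].
#' @param nodes_to_delete character vector of nodes to knock out, one
#'   scenario per node.
#' @return list with `full` (class counts of the full model, plus the
#'   full `dependency_matrix` as attribute `dm`) and `scenarios`, a
#'   named list per deleted node of `list(counts, delta)`.
#' @export
ko_scenario_report <- function(net, nodes_to_delete) {
  stopifnot(inherits(net, "signed_network"))
  dm_full <- dependency_matrix(net)
  scenarios <- lapply(setNames(nodes_to_delete, nodes_to_delete), function(v) {
    dm_ko <- dependency_matrix(knockout(net, v))
    list(counts = class_counts(dm_ko), delta = dm_delta(dm_full, dm_ko))
  })
  full <- class_counts(dm_full)
  attr(full, "dm") <- dm_full
  list(full = full, scenarios = scenarios)
}

#' Write a dependency matrix as TSV
#'
#' Node-labelled rows and columns with class abbreviations
#' (`NE`, `AMB`, `WI`, `SI`, `WA`, `SA`). Rows are the acting node,
#' columns the affected node.
#'
#' @param dm a [dependency_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_depmat <- function(dm, path) {
  stopifnot(inherits(dm, "dependency_matrix"))
  ab <- matrix(.dep_abbrev[dm], nrow(dm), dimnames = dimnames(dm))
  write.table(data.frame(node = rownames(ab), ab, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Heatmap of a dependency matrix
#'
#' Base-graphics image using the conventional colour code: no effect
#' black, ambivalent yellow, weak inhibitor pink, strong inhibitor
#' red, weak activator light green, strong activator dark green. The
#' y-axis node acts on the x-axis node.
#'
#' @param x a [dependency_matrix()].
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.dependency_matrix <- function(x, ...) {
  lev <- dependency_classes()
  cols <- c(NO_EFFECT = "black", AMBIVALENT = "yellow",
            WEAK_INHIBITOR = "pink", WEAK_ACTIVATOR = "lightgreen",
            STRONG_INHIBITOR = "red", STRONG_ACTIVATOR = "darkgreen")
  z <- matrix(match(unclass(x), lev), nrow(x))
  n <- nrow(x)
  ## image() draws columns left-to-right, rows bottom-up; transpose so
  ## the acting node runs down the y-axis
  graphics::image(seq_len(n), seq_len(n), t(z[n:1, , drop = FALSE]),
                  col = cols[lev], zlim = c(1, 6), axes = FALSE,
                  xlab = "affected node", ylab = "acting node", ...)
  graphics::axis(1, at = seq_len(n), labels = colnames(x), las = 2, cex.axis = 0.6)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(x)), las = 2, cex.axis = 0.6)
  invisible(x)
}
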