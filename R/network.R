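#' Construct a signed interaction network
#'
#' A signed network is a directed multigraph whose edges carry a sign:
#' `+1` for activation, `-1` for inhibition. Parallel edges of opposite
#' sign between the same pair of nodes are permitted (a pair can be
#' both activated and inhibited), as are self-edges. Exact duplicate
#' records (same source, target and sign) are collapsed to their first
#' occurrence with a warning.
#'
#' @param edges data.frame with columns `source`, `target` (non-empty
#'   character node names) and `sign` (`+1` or `-1`); an optional
#'   `evidence` column holds supporting PubMed IDs (";"-separated).
#' @param nodes optional character vector of node names; must contain
#'   every edge endpoint. Extra names become isolated nodes. Defaults
#'   to the endpoints in order of first appearance.
#' @return An object of class `signed_network`: a list with `nodes`
#'   (character) and `edges` (data.frame `source`, `target`, `sign`,
#'   `evidence`).
#' @examples
#' net <- signed_network(data.frame(
#'   source = c("SORL1", "SORL1"), target = c("APP", "BACE1"),
#'   sign = c(1, -1)))
#' net
#' @export
signed_network <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) == 0L) {
    edges <- data.frame(source = character(), target = character(),
                        sign = integer(), evidence = character())
  }
  required <- c("source", "target", "sign")
  missing_cols <- setdiff(required, names(edges))
  if (length(missing_cols)) {
    stop("edges is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$sign <- as.integer(edges$sign)
  if (is.null(edges$evidence)) edges$evidence <- NA_character_
  edges$evidence <- as.character(edges$evidence)
  if (any(!edges$sign %in% c(-1L, 1L))) {
    stop("edge signs must be +1 (activation) or -1 (inhibition)")
  }
  if (any(!nzchar(edges$source)) || any(!nzchar(edges$target))) {
    stop("edge endpoints must be non-empty node names")
  }
  key <- paste(edges$source, edges$target, edges$sign, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate interaction record(s) collapsed")
    edges <- edges[!dup, , drop = FALSE]
  }
  endpoint_order <- unique(c(rbind(edges$source, edges$target)))
  if (is.null(nodes)) {
    nodes <- endpoint_order
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) stop("duplicate node names")
    absent <- setdiff(endpoint_order, nodes)
    if (length(absent)) {
      stop("edge endpoints not in node set: ", paste(absent, collapse = ", "))
    }
  }
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  n_act <- sum(x$edges$sign == 1L)
  cat(sprintf("signed_network: %d nodes, %d edges (%d activating, %d inhibiting)\n",
              length(x$nodes), nrow(x$edges), n_act, nrow(x$edges) - n_act))
  invisible(x)
}

#' @export
format.signed_network <- function(x, ...) {
  sprintf("<signed_network: %d nodes, %d edges>", length(x$nodes), nrow(x$edges))
}

.default_sign_tokens <- function() {
  list(activation = c("activates", "+", "1", "+1"),
       inhibition = c("inhibits", "-", "-1", "\u2212", paste0("\u2212", "1")))
}

.parse_sign <- function(token, sign_tokens, line) {
  tok <- trimws(token)
  if (tok %in% sign_tokens$activation) return(1L)
  if (tok %in% sign_tokens$inhibition) return(-1L)
  stop(sprintf(
    "line %d: unknown sign token '%s' (accepted: %s)", line, tok,
    paste(c(sign_tokens$activation, sign_tokens$inhibition), collapse = ", ")),
    call. = FALSE)
}

#' Read a signed interaction network from a file
#'
#' Two dialects are supported. `"sif"` is a headerless, tab-delimited
#' simple-interaction format, one edge per line
#' (`source<TAB>sign<TAB>target`), with `#` comment lines permitted.
#' `"evidence_table"` is a delimited file with a header row naming the
#' source, interaction (sign), target and optional PubMed-ID columns,
#' as exported from curated interaction records.
#'
#' Sign tokens are configurable; the defaults accept
#' `activates`/`+`/`1` for activation and `inhibits`/`-`/`-1` for
#' inhibition. Duplicate records are collapsed (with a warning) and
#' edge order follows first occurrence. Node names are matched
#' case-sensitively and exactly: no gene-symbol aliasing is attempted,
#' so near-identical symbols in the input (e.g. `GRFA1` vs `GFRA1`)
#' surface as distinct nodes for the curator to resolve.
#'
#' @param path path to the interaction file.
#' @param dialect `"sif"` or `"evidence_table"`.
#' @param sign_tokens list with character vectors `activation` and
#'   `inhibition` of accepted sign tokens.
#' @param columns for `evidence_table`: named character vector mapping
#'   roles `source`, `interaction`, `target`, `pmid` to header names.
#' @param sep field separator for `evidence_table` (`"\t"` or `","`).
#' @return A [signed_network()].
#' @seealso [write_interactions()]
#' @examples
#' f <- tempfile(fileext = ".sif")
#' writeLines(c("SORL1\t+\tAPP", "SORL1\t-\tAPOA5"), f)
#' read_interactions(f)
#' @export
read_interactions <- function(path,
                              dialect = c("sif", "evidence_table"),
                              sign_tokens = .default_sign_tokens(),
                              columns = c(source = "source",
                                          interaction = "interaction",
                                          target = "target",
                                          pmid = "pmid"),
                              sep = "\t") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "sif") {
    lines <- readLines(path, warn = FALSE)
    keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
    recs <- lapply(keep, function(i) {
      fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
      fields <- trimws(fields)
      if (length(fields) < 3L || any(!nzchar(fields[1:3]))) {
        stop(sprintf("line %d: expected 'source<TAB>sign<TAB>target', got '%s'",
                     i, lines[[i]]), call. = FALSE)
      }
      data.frame(source = fields[[1]],
                 sign = .parse_sign(fields[[2]], sign_tokens, i),
                 target = fields[[3]],
                 evidence = if (length(fields) >= 4L) fields[[4]] else NA_character_)
    })
    edges <- if (length(recs)) {
      do.call(rbind, c(recs, list(make.row.names = FALSE)))
    } else {
      data.frame(source = character(), target = character(),
                 sign = integer(), evidence = character())
    }
  } else {
    tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                      check.names = FALSE)
    for (role in c("source", "interaction", "target")) {
      if (!columns[[role]] %in% names(tab)) {
        stop(sprintf("evidence_table is missing the '%s' column ('%s')",
                     role, columns[[role]]))
      }
    }
    sgn <- vapply(seq_len(nrow(tab)), function(i) {
      .parse_sign(tab[[columns[["interaction"]]]][i], sign_tokens, i + 1L)
    }, integer(1))
    ev <- if (columns[["pmid"]] %in% names(tab)) {
      as.character(tab[[columns[["pmid"]]]])
    } else NA_character_
    edges <- data.frame(source = as.character(tab[[columns[["source"]]]]),
                        target = as.character(tab[[columns[["target"]]]]),
                        sign = sgn, evidence = ev)
  }
  signed_network(edges)
}

#' Write a signed interaction network to a file
#'
#' Inverse of [read_interactions()]: a read/write/read round trip is
#' the identity on deduplicated networks. The `sif` dialect writes
#' `source<TAB>sign<TAB>target` rows with `+`/`-` sign tokens; the
#' `evidence_table` dialect writes a header plus a `pmid` column.
#' Isolated nodes are not representable in either dialect and are
#' dropped with a warning.
#'
#' @inheritParams read_interactions
#' @param net a [signed_network()].
#' @return `path`, invisibly.
#' @export
write_interactions <- function(net, path, dialect = c("sif", "evidence_table"),
                               sep = "\t") {
  stopifnot(inherits(net, "signed_network"))
  dialect <- match.arg(dialect)
  isolated <- setdiff(net$nodes, c(net$edges$source, net$edges$target))
  if (length(isolated)) {
    warning("isolated node(s) not representable in edge-list output: ",
            paste(isolated, collapse = ", "))
  }
  sign_tok <- ifelse(net$edges$sign == 1L, "+", "-")
  if (dialect == "sif") {
    writeLines(paste(net$edges$source, sign_tok, net$edges$target, sep = "\t"),
               path)
  } else {
    out <- data.frame(source = net$edges$source, interaction = sign_tok,
                      target = net$edges$target, pmid = net$edges$evidence)
    write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Node degrees and degree histogram
#'
#' The degree of a node is its number of edge incidences (as source
#' plus as target). By default a self-edge therefore contributes 2 to
#' its node's degree, which makes the degree sum exactly twice the edge
#' count; set `self_loops = "single"` to count self-edges once.
#'
#' @param net a [signed_network()].
#' @param self_loops `"double"` (default) or `"single"`.
#' @return list with `degrees` (named integer vector over all nodes)
#'   and `histogram` (data.frame `degree`, `n_nodes`).
#' @examples
#' net <- signed_network(data.frame(source = "A", target = "B", sign = 1))
#' degree_distribution(net)$degrees
#' @export
degree_distribution <- function(net, self_loops = c("double", "single")) {
  stopifnot(inherits(net, "signed_network"))
  self_loops <- match.arg(self_loops)
  src <- table(factor(net$edges$source, levels = net$nodes))
  tgt <- table(factor(net$edges$target, levels = net$nodes))
  deg <- as.integer(src + tgt)
  names(deg) <- net$nodes
  if (self_loops == "single") {
    self <- table(factor(net$edges$source[net$edges$source == net$edges$target],
                         levels = net$nodes))
    deg <- deg - as.integer(self)
    names(deg) <- net$nodes
  }
  hist_tab <- table(deg)
  histogram <- data.frame(degree = as.integer(names(hist_tab)),
                          n_nodes = as.integer(hist_tab))
  list(degrees = deg, histogram = histogram)
}

#' Delete a node from a network (structural knockout)
#'
#' Simulates loss of a gene/protein for dependency-matrix analysis by
#' removing the node and every edge incident to it. The input network
#' is not modified. (For logical steady-state knockouts the node is
#' instead clamped to 0 in the scenario; see [compute_lss()].)
#'
#' @param net a [signed_network()].
#' @param node name of the node to delete.
#' @return A new [signed_network()] without `node`.
#' @examples
#' net <- signed_network(data.frame(source = "A", target = "B", sign = 1))
#' knockout(net, "B")
#' @export
knockout <- function(net, node) {
  stopifnot(inherits(net, "signed_network"), length(node) == 1L)
  if (!node %in% net$nodes) stop("node not in network: ", node)
  keep <- net$edges$source != node & net$edges$target != node
  signed_network(net$edges[keep, , drop = FALSE],
                 nodes = setdiff(net$nodes, node))
}
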