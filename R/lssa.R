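## Three-valued logic helpers. States live in {0, 1, NaN}; the
## "activity order" is 1 > NaN > 0. NaN propagates Kleene-style:
## NOT NaN = NaN; OR is 1 if any operand is 1, 0 if all are 0, else NaN.

.t_not <- function(x) ifelse(is.nan(x), NaN, 1 - x)

.t_or <- function(x) {
  if (any(x == 1, na.rm = TRUE)) return(1)
  if (length(x) && all(!is.nan(x) & x == 0)) return(0)
  NaN
}

## 1 -> 2, NaN -> 1, 0 -> 0 on the activity order
.t_level <- function(x) ifelse(is.nan(x), 1, 2 * x)

#' Compute the logical steady state of a signed network
#'
#' Three-valued logical steady-state analysis (LSSA). Every node takes
#' a value in \{1, 0, `NaN`\}: ON, OFF, or undetermined, with 1
#' considered more active than `NaN` and `NaN` more active than 0.
#' All nodes start at `NaN`; the scenario clamps input nodes to 0 or
#' 1; values then propagate until a fixpoint is reached.
#'
#' Each edge acts as a one-tail influence on its target: an activating
#' edge contributes the source's value, an inhibiting edge contributes
#' the three-valued negation of the source's value (`NOT 1 = 0`,
#' `NOT 0 = 1`, `NOT NaN = NaN`). A non-clamped node with incoming
#' edges takes the three-valued OR of its incoming influences (1 if
#' any influence is 1; 0 if all are 0; else `NaN`); a non-clamped node
#' with no incoming edges stays `NaN`. Updates are synchronous
#' (Jacobi-style), which makes the result independent of node order;
#' convergence is guaranteed because a value can only move from `NaN`
#' to 0/1, never back. Nodes inside cycles whose values are never
#' forced by the clamped inputs remain `NaN` (undetermined /
#' potentially oscillatory); no attractor enumeration is attempted.
#'
#' @param net a [signed_network()].
#' @param scenario named numeric vector of clamped values in \{0, 1\};
#'   names must be network nodes. E.g. `c(SORL1 = 1)` for a wild-type
#'   scenario and `c(SORL1 = 0)` for a knockout scenario.
#' @return An object of class `ternary_state`: list with `values`
#'   (named numeric over all nodes, in \{0, 1, NaN\}), `clamped`
#'   (character) and `iterations`.
#' @examples
#' net <- signed_network(data.frame(source = c("A", "A"),
#'                                  target = c("B", "C"),
#'                                  sign = c(1, -1)))
#' compute_lss(net, c(A = 1))$values
#' @export
compute_lss <- function(net, scenario) {
  stopifnot(inherits(net, "signed_network"))
  scenario <- unlist(scenario)
  if (length(scenario)) {
    if (is.null(names(scenario)) || any(!nzchar(names(scenario)))) {
      stop("scenario must be a named vector")
    }
    unknown <- setdiff(names(scenario), net$nodes)
    if (length(unknown)) {
      stop("scenario clamps unknown node(s): ", paste(unknown, collapse = ", "))
    }
    if (any(!scenario %in% c(0, 1))) stop("clamped values must be 0 or 1")
  }
  values <- setNames(rep(NaN, length(net$nodes)), net$nodes)
  clamped <- if (length(scenario)) names(scenario) else character(0)
  values[clamped] <- scenario
  free <- setdiff(net$nodes, clamped)
  ## incoming influences per free node: list of (source index, sign)
  in_edges <- lapply(setNames(free, free), function(v) {
    sel <- net$edges$target == v
    list(src = net$edges$source[sel], sign = net$edges$sign[sel])
  })
  iter <- 0L
  repeat {
    iter <- iter + 1L
    new_values <- values
    for (v in free) {
      ie <- in_edges[[v]]
      if (!length(ie$src)) next  # no inputs: stays NaN
      tails <- values[ie$src]
      tails[ie$sign == -1L] <- .t_not(tails[ie$sign == -1L])
      new_values[[v]] <- .t_or(tails)
    }
    if (identical(is.nan(new_values), is.nan(values)) &&
        isTRUE(all(new_values == values | is.nan(new_values)))) break
    values <- new_values
    if (iter > length(net$nodes) + 1L) break  # monotone: cannot recur
  }
  structure(list(values = values, clamped = clamped, iterations = iter),
            class = "ternary_state")
}

#' @export
print.ternary_state <- function(x, ...) {
  cat(sprintf("ternary_state over %d nodes (%d clamped): %d ON, %d OFF, %d NaN\n",
              length(x$values), length(x$clamped),
              sum(x$values == 1, na.rm = TRUE),
              sum(x$values == 0, na.rm = TRUE),
              sum(is.nan(x$values))))
  invisible(x)
}

#' Model-predicted change between two logical steady states
#'
#' Compares a reference (wild-type) steady state with a perturbed
#' (knockout) steady state node by node and returns the model's
#' prediction `Emod` in \{-1, 0, +1\}: `-1` if the node is less active
#' in the perturbed scenario (down-regulated in the mutant), `+1` if
#' more active (up-regulated), `0` if its level is unchanged, on the
#' activity order 1 > `NaN` > 0. The criterion node (the clamped
#' perturbation target), and any other clamped node, is reported as
#' excluded: it was manually set, not predicted.
#'
#' @param state_wt,state_ko [compute_lss()] results over the same node
#'   set; `state_ko` may lack the criterion node (structural knockout).
#' @param criterion name of the perturbed node.
#' @return An object of class `emod_vector`: named integer vector of
#'   predictions over the common non-criterion nodes, with attribute
#'   `excluded` (criterion plus clamped nodes).
#' @examples
#' net <- signed_network(data.frame(source = "A", target = "B", sign = 1))
#' wt <- compute_lss(net, c(A = 1))
#' ko <- compute_lss(net, c(A = 0))
#' emod(wt, ko, "A")
#' @export
emod <- function(state_wt, state_ko, criterion) {
  stopifnot(inherits(state_wt, "ternary_state"),
            inherits(state_ko, "ternary_state"),
            length(criterion) == 1L)
  nodes_wt <- names(state_wt$values)
  nodes_ko <- names(state_ko$values)
  if (!criterion %in% nodes_wt) stop("criterion not in wild-type state: ", criterion)
  mismatch <- c(setdiff(setdiff(nodes_wt, criterion), nodes_ko),
                setdiff(nodes_ko, nodes_wt))
  if (length(mismatch)) {
    stop("state node sets differ beyond the criterion node: ",
         paste(mismatch, collapse = ", "))
  }
  excluded <- unique(c(criterion, state_wt$clamped, state_ko$clamped))
  common <- setdiff(nodes_wt, criterion)
  delta <- .t_level(state_ko$values[common]) - .t_level(state_wt$values[common])
  out <- setNames(as.integer(sign(delta)), common)
  structure(out, excluded = excluded, class = "emod_vector")
}

#' @export
print.emod_vector <- function(x, ...) {
  s <- emod_summary(x)
  cat(sprintf("emod_vector: %d up, %d down, %d unchanged (%d excluded)\n",
              s[["up"]], s[["down"]], s[["unchanged"]],
              length(attr(x, "excluded"))))
  invisible(x)
}

#' Summarise an Emod vector
#'
#' Counts the up-regulated (+1), down-regulated (-1) and unchanged (0)
#' predictions over the non-excluded nodes.
#'
#' @param vec an [emod()] result.
#' @return Named integer vector `c(up, down, unchanged)`.
#' @export
emod_summary <- function(vec) {
  stopifnot(inherits(vec, "emod_vector"))
  v <- vec[!names(vec) %in% attr(vec, "excluded")]
  c(up = sum(v == 1L), down = sum(v == -1L), unchanged = sum(v == 0L))
}

#' Read a scenario file
#'
#' Two-column tab-delimited file `node<TAB>value` with values 0 or 1;
#' `#` comments permitted.
#'
#' @param path file path.
#' @return named numeric vector usable as `scenario` in [compute_lss()].
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  vals <- numeric(0)
  for (i in keep) {
    fields <- trimws(strsplit(lines[[i]], "\t", fixed = TRUE)[[1]])
    if (length(fields) != 2L || !fields[[2]] %in% c("0", "1")) {
      stop(sprintf("line %d: expected 'node<TAB>0|1', got '%s'", i, lines[[i]]))
    }
    vals[fields[[1]]] <- as.numeric(fields[[2]])
  }
  vals
}

#' Write a steady state (with optional Emod column) to TSV
#'
#' @param state a [compute_lss()] result.
#' @param path output path.
#' @param emod optional [emod()] result to append as a third column
#'   (`NA` for excluded nodes).
#' @return `path`, invisibly.
#' @export
write_state <- function(state, path, emod = NULL) {
  stopifnot(inherits(state, "ternary_state"))
  val <- ifelse(is.nan(state$values), "NaN", format(state$values))
  out <- data.frame(node = names(state$values), value = val)
  if (!is.null(emod)) {
    stopifnot(inherits(emod, "emod_vector"))
    out$emod <- ifelse(out$node %in% attr(emod, "excluded"), NA_integer_,
                       unname(emod[out$node]))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
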