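## Seed-deterministic generators for every input the pipeline consumes:
## hub-centred signed networks, WT/KO replicate expression matrices with
## planted directional effects, and patient cohorts in which a focal
## gene's expression stratifies patients.

.with_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

#' Generate a random signed network
#'
#' In hub mode (the default) the topology emulates a curated
#' two-layer signalling network centred on one focal gene: the focal
#' node sends an edge to a fraction of the other nodes (default all of
#' them) and receives edges back from a smaller fraction (default
#' 1/3), and the remaining edge budget is spent on random edges among
#' the periphery. With the default 34 nodes and 92 edges the focal
#' node has degree 33 + 11 = 44, strictly above every other node, and
#' the periphery carries the remaining 48 edges. Edge signs are
#' activating with probability `activation_fraction` (default 0.75;
#' curated signalling maps are predominantly activating).
#'
#' Periphery edges are sampled so that no other node's degree can
#' reach the focal node's; the focal node's degree is therefore
#' strictly maximal by construction.
#'
#' @param n_nodes,n_edges network size (defaults 34 nodes, 92 edges).
#' @param activation_fraction probability that an edge activates.
#' @param hub logical; wire a focal hub node (default `TRUE`). If
#'   `FALSE`, all edges are sampled uniformly over ordered node pairs.
#' @param hub_out_fraction,hub_in_fraction fraction of the other nodes
#'   the focal node sends edges to / receives edges from.
#' @param node_names optional node names (first is the focal node);
#'   defaults to `N01`, `N02`, ...
#' @param seed integer seed; identical seeds give identical networks.
#' @return A [signed_network()] with attribute `focal` (the hub node
#'   name, hub mode only).
#' @examples
#' net <- gen_network(seed = 1)
#' max(degree_distribution(net)$degrees)
#' @export
gen_network <- function(n_nodes = 34, n_edges = 92, activation_fraction = 0.75,
                        hub = TRUE, hub_out_fraction = 1,
                        hub_in_fraction = 1 / 3, node_names = NULL,
                        seed = NULL) {
  stopifnot(n_nodes >= 2, activation_fraction >= 0, activation_fraction <= 1,
            hub_out_fraction >= 0, hub_out_fraction <= 1,
            hub_in_fraction >= 0, hub_in_fraction <= 1)
  if (is.null(node_names)) {
    node_names <- sprintf("N%02d", seq_len(n_nodes))
  }
  stopifnot(length(node_names) == n_nodes)
  .with_seed(seed, {
    if (hub) {
      focal <- node_names[[1]]
      others <- node_names[-1]
      n_out <- round(hub_out_fraction * length(others))
      n_in <- round(hub_in_fraction * length(others))
      hub_deg <- n_out + n_in
      if (n_edges < hub_deg) {
        stop("edge budget (", n_edges, ") below hub degree (", hub_deg, ")")
      }
      out_t <- sample(others, n_out)
      in_s <- sample(others, n_in)
      edges <- data.frame(source = c(rep(focal, n_out), in_s),
                          target = c(out_t, rep(focal, n_in)))
      ## periphery edges: keep every periphery degree below the hub's
      n_rest <- n_edges - hub_deg
      cand <- expand.grid(source = others, target = others,
                          stringsAsFactors = FALSE)
      cand <- cand[cand$source != cand$target, , drop = FALSE]
      cand <- cand[sample(nrow(cand)), , drop = FALSE]
      deg <- setNames(integer(length(others)), others)
      deg[out_t] <- deg[out_t] + 1L
      deg[in_s] <- deg[in_s] + 1L
      taken <- 0L
      keep <- logical(nrow(cand))
      for (i in seq_len(nrow(cand))) {
        if (taken == n_rest) break
        u <- cand$source[i]; v <- cand$target[i]
        if (deg[[u]] + 1L < hub_deg && deg[[v]] + 1L < hub_deg) {
          keep[i] <- TRUE
          deg[[u]] <- deg[[u]] + 1L
          deg[[v]] <- deg[[v]] + 1L
          taken <- taken + 1L
        }
      }
      if (taken < n_rest) {
        stop("cannot place ", n_rest, " periphery edges under the ",
             "hub-degree constraint")
      }
      edges <- rbind(edges, cand[keep, , drop = FALSE])
    } else {
      focal <- NULL
      cand <- expand.grid(source = node_names, target = node_names,
                          stringsAsFactors = FALSE)
      cand <- cand[cand$source != cand$target, , drop = FALSE]
      if (n_edges > nrow(cand)) stop("edge budget exceeds graph capacity")
      edges <- cand[sample(nrow(cand), n_edges), , drop = FALSE]
    }
    edges$sign <- ifelse(stats::runif(nrow(edges)) < activation_fraction, 1L, -1L)
    net <- signed_network(edges, nodes = node_names)
    if (hub) {
      deg_all <- degree_distribution(net)$degrees
      stopifnot(deg_all[[focal]] > max(deg_all[names(deg_all) != focal]))
      attr(net, "focal") <- focal
    }
    net
  })
}

#' Generate a WT/KO replicate expression matrix with planted effects
#'
#' Emulates a knockout RNA-seq experiment with replicate samples per
#' condition. Each gene carries a target change direction (a model
#' prediction in \{-1, 0, +1\}); with probability `agreement` the
#' planted KO/WT mean ratio follows that direction (`multiplier`,
#' its reciprocal, or unity), otherwise the planted direction is drawn
#' uniformly from the other two options. Replicate values are
#' log-normal around the condition means, so fold changes of means are
#' always positive and well-defined. Per-gene q-values are computed by
#' a Welch t-test on log values across replicates with
#' Benjamini-Hochberg adjustment and stored in the returned matrix.
#'
#' @param target_emod named integer vector in \{-1, 0, +1\}: the
#'   change direction each gene should show (names are genes).
#' @param agreement probability that a gene's planted direction equals
#'   its target.
#' @param replicates samples per condition (default 4).
#' @param baseline_mean typical WT expression level (default 100);
#'   per-gene baselines vary log-normally around it.
#' @param sdlog replicate noise (log-normal sigma, default 0.15).
#' @param multiplier planted effect size, KO/WT mean ratio for an
#'   up-regulated gene (> 1; default 4).
#' @param group group (cell-type) label for the samples.
#' @param seed integer seed.
#' @return list with `expr` (an [expression_matrix()] with q-values)
#'   and `truth` (data.frame `gene`, `target`, `planted`).
#' @export
gen_cellline_expr <- function(target_emod, agreement = 1, replicates = 4,
                              baseline_mean = 100, sdlog = 0.15,
                              multiplier = 4, group = "cellline",
                              seed = NULL) {
  stopifnot(!is.null(names(target_emod)), all(target_emod %in% -1:1),
            agreement >= 0, agreement <= 1, replicates >= 2, multiplier > 1)
  genes <- names(target_emod)
  .with_seed(seed, {
    planted <- vapply(target_emod, function(d) {
      if (stats::runif(1) < agreement) d else sample(setdiff(-1:1, d), 1L)
    }, numeric(1))
    base <- baseline_mean * rlnorm(length(genes), 0, 0.5)
    ko_mean <- base * multiplier^planted
    n <- 2L * replicates
    draw <- function(mu) rlnorm(replicates, log(mu) - sdlog^2 / 2, sdlog)
    values <- t(vapply(seq_along(genes), function(i) {
      c(draw(base[[i]]), draw(ko_mean[[i]]))
    }, numeric(n)))
    dimnames(values) <- list(genes,
                             c(paste0(group, "_WT_", seq_len(replicates)),
                               paste0(group, "_KO_", seq_len(replicates))))
    condition <- rep(c("WT", "KO"), each = replicates)
    p <- vapply(seq_along(genes), function(i) {
      t.test(log(values[i, condition == "KO"]),
             log(values[i, condition == "WT"]))$p.value
    }, numeric(1))
    qvalues <- matrix(p.adjust(p, "BH"), ncol = 1,
                      dimnames = list(genes, group))
    expr <- expression_matrix(values, condition,
                              rep(group, n), qvalues = qvalues)
    list(expr = expr,
         truth = data.frame(gene = genes, target = as.integer(target_emod),
                            planted = as.integer(planted), row.names = NULL))
  })
}

#' Generate a patient cohort stratifiable by a focal gene
#'
#' Draws a continuous (log-normal) expression value of the focal gene
#' for each patient, then gives each other gene a signed log-linear
#' response to the standardised log focal value plus log-normal noise.
#' Genes with association sign 0 (or effect size 0) are null genes.
#'
#' @param genes character vector of gene names (must include
#'   `focal_gene`).
#' @param focal_gene the stratifying gene.
#' @param assoc_sign named integer vector in \{-1, 0, +1\} over the
#'   non-focal genes (recycled scalar allowed): direction of each
#'   gene's association with the focal gene.
#' @param effect_size log-scale response per SD of log focal
#'   expression (scalar or named vector; default 1).
#' @param n_patients cohort size (default 100).
#' @param baseline_mean typical expression level (default 100).
#' @param sdlog per-gene residual noise (default 0.3).
#' @param focal_sdlog spread of the focal gene across patients
#'   (default 0.5).
#' @param seed integer seed.
#' @return list with `cohort` (patient-by-gene matrix, patient IDs
#'   `P001`, ...) and `truth` (data.frame `gene`, `sign`, `effect`).
#' @export
gen_cohort <- function(genes, focal_gene, assoc_sign = 0, effect_size = 1,
                       n_patients = 100, baseline_mean = 100, sdlog = 0.3,
                       focal_sdlog = 0.5, seed = NULL) {
  stopifnot(focal_gene %in% genes, n_patients >= 4)
  others <- setdiff(genes, focal_gene)
  if (length(assoc_sign) == 1L && is.null(names(assoc_sign))) {
    assoc_sign <- setNames(rep(as.integer(assoc_sign), length(others)), others)
  }
  if (length(effect_size) == 1L && is.null(names(effect_size))) {
    effect_size <- setNames(rep(effect_size, length(others)), others)
  }
  stopifnot(all(others %in% names(assoc_sign)),
            all(others %in% names(effect_size)),
            all(assoc_sign %in% -1:1))
  .with_seed(seed, {
    focal <- rlnorm(n_patients, log(baseline_mean), focal_sdlog)
    s <- as.numeric(scale(log(focal)))
    cohort <- matrix(NA_real_, n_patients, length(genes),
                     dimnames = list(sprintf("P%03d", seq_len(n_patients)),
                                     genes))
    cohort[, focal_gene] <- focal
    for (g in others) {
      mu <- log(baseline_mean) + assoc_sign[[g]] * effect_size[[g]] * s
      cohort[, g] <- rlnorm(n_patients, mu - sdlog^2 / 2, sdlog)
    }
    truth <- data.frame(gene = others,
                        sign = as.integer(assoc_sign[others]),
                        effect = unname(effect_size[others]),
                        row.names = NULL)
    list(cohort = cohort, truth = truth)
  })
}
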