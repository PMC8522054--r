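# Weighted gene-interaction network proximity analysis: build the
# thresholded graph, average shortest distances between gene sets, and the
# node-relabelling permutation test.

#' Build a thresholded weighted gene network
#'
#' Edges with probability weight <= `threshold` are dropped (strict >),
#' duplicates collapse to the maximum probability, self-loops are removed,
#' and each retained edge gets path weight 1/probability.
#'
#' @param edges data.frame(geneA, geneB, probability).
#' @param threshold probability retention threshold (default 2.0).
#' @return igraph undirected graph with `probability` and `weight`
#'   (inverse probability) edge attributes.
#' @export
build_network <- function(edges, threshold = 2.0) {
  if (any(edges$probability <= 0))
    stop_twohit("edge probabilities must be positive")
  e <- edges[edges$probability > threshold, , drop = FALSE]
  e <- e[e$geneA != e$geneB, , drop = FALSE]
  # collapse duplicates (either orientation) keeping the max probability
  a <- pmin(e$geneA, e$geneB); b <- pmax(e$geneA, e$geneB)
  key <- paste(a, b)
  keep <- tapply(seq_len(nrow(e)), key, function(i)
    i[which.max(e$probability[i])])
  e <- e[unlist(keep), , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$geneA, to = e$geneB,
               probability = e$probability,
               weight = 1 / e$probability), directed = FALSE)
  g
}

#' Average shortest weighted distance between two gene sets
#'
#' Dijkstra shortest paths (inverse-probability weights) for every
#' ordered pair (a, b), a in `setA`, b in `setB`, a != b; the mean is
#' taken over connected pairs, and genes absent from the network are
#' dropped (counts reported).
#'
#' @param g network from [build_network()].
#' @param setA,setB gene-id vectors (second-hit genes and
#'   expression-change genes).
#' @return list(mean_distance, n_pairs, n_disconnected, n_dropped).
#' @export
avg_min_distance <- function(g, setA, setB) {
  nodes <- igraph::V(g)$name
  a <- unique(setA[setA %in% nodes])
  b <- unique(setB[setB %in% nodes])
  n_dropped <- (length(unique(setA)) - length(a)) +
    (length(unique(setB)) - length(b))
  if (!length(a) || !length(b))
    stop_twohit("no set members present in the network")
  dm <- igraph::distances(g, v = a, to = b, weights = igraph::E(g)$weight,
                          algorithm = "dijkstra")
  same <- outer(a, b, "==")
  dm[same] <- NA
  vals <- dm[!is.na(dm)]
  finite <- vals[is.finite(vals)]
  if (!length(finite)) stop_twohit("no connected pair between the sets")
  list(mean_distance = mean(finite), n_pairs = length(finite),
       n_disconnected = sum(!is.finite(vals)), n_dropped = n_dropped)
}

#' Node-relabelling permutation test of network proximity
#'
#' Permutes the gene-to-node assignment uniformly over all nodes
#' (topology fixed), recomputes the average shortest distance between the
#' relabelled sets `n` times, and reports `z = (permuted mean - observed)
#' / permuted SD` with one-tailed `p = Phi(-z)` for the "observed
#' smaller" alternative, plus the empirical permutation p-value
#' `(1 + #{perm <= obs}) / (n + 1)`.
#'
#' @param g network; `setA`, `setB` gene sets.
#' @param n number of permutations (default 100).
#' @param seed integer seed for the permutations.
#' @return list(observed, permuted_mean, permuted_sd, z, p, p_empirical,
#'   n_perm, n_pairs).
#' @export
permutation_test <- function(g, setA, setB, n = 100, seed = 1) {
  obs <- avg_min_distance(g, setA, setB)
  nodes <- igraph::V(g)$name
  with_seed(seed, {
    perm <- vapply(seq_len(n), function(i) {
      relabel <- setNames(sample(nodes), nodes)
      pa <- unname(relabel[setA[setA %in% nodes]])
      pb <- unname(relabel[setB[setB %in% nodes]])
      tryCatch(avg_min_distance(g, pa, pb)$mean_distance,
               error = function(e) NA_real_)
    }, numeric(1))
  })
  perm <- perm[!is.na(perm)]
  pm <- mean(perm); psd <- sd(perm)
  if (!length(perm) || is.na(psd) || psd == 0) {
    warning("permuted SD is zero; z undefined")
    return(list(observed = obs$mean_distance, permuted_mean = pm,
                permuted_sd = psd, z = NA_real_, p = NA_real_,
                p_empirical = NA_real_, n_perm = length(perm),
                n_pairs = obs$n_pairs))
  }
  z <- (pm - obs$mean_distance) / psd
  list(observed = obs$mean_distance, permuted_mean = pm,
       permuted_sd = psd, z = z, p = pnorm(-z),
       p_empirical = (1 + sum(perm <= obs$mean_distance)) /
         (length(perm) + 1),
       n_perm = length(perm), n_pairs = obs$n_pairs)
}

#' Cohort-level paired test of network proximity
#'
#' Paired two-sided Wilcoxon signed-rank test of (observed, permuted
#' mean) average distances across offspring.
#'
#' @param observed,permuted_mean numeric vectors, one entry per offspring
#'   (>= 5).
#' @return list(statistic, p.value, method).
#' @export
cohort_proximity_test <- function(observed, permuted_mean) {
  if (length(observed) < 5) stop_twohit("need >= 5 offspring")
  signed_rank_test(observed, permuted_mean)
}

#' Parse a weighted edge list from TSV
#'
#' Tolerant parse with header auto-detection; weights must be numeric.
#'
#' @param path TSV with columns geneA, geneB, probability (header
#'   optional).
#' @return data.frame(geneA, geneB, probability).
#' @export
parse_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop_twohit("empty edge list")
  first <- strsplit(lines[1], "\t")[[1]]
  has_header <- is.na(suppressWarnings(as.numeric(first[3])))
  start <- if (has_header) 2L else 1L
  rows <- lapply(seq(start, length(lines)), function(i) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) < 3)
      stop_twohit("malformed edge-list row at line ", i)
    w <- suppressWarnings(as.numeric(f[3]))
    if (is.na(w))
      stop_twohit("non-numeric weight at line ", i)
    data.frame(geneA = f[1], geneB = f[2], probability = w,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
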