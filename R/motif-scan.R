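# Motif enumeration and reactivity scanning.
#
# Motif classes over induced trophic subgraphs:
#   PP     predator-prey link (2 nodes)
#   AC     apparent competition: one predator consuming two prey
#   EC     exploitative competition: two consumers sharing one prey
#   TTC    tritrophic chain i -> j -> k
#   OTHER3 any other weakly connected 3-node induced pattern (e.g. omnivory)
# Classification is an exact census on the induced link set, so the classes
# are disjoint.

# Internal: links as ascending node pairs, deduplicated (a mutual-predation
# pair is one 2-node instance: its reactivity depends only on the node set).
link_census <- function(web) {
  e <- which(web$adjacency, arr.ind = TRUE)
  n1 <- pmin(e[, 1], e[, 2])
  n2 <- pmax(e[, 1], e[, 2])
  keep <- !duplicated(cbind(n1, n2))
  ord <- order(n1[keep], n2[keep])
  list(n1 = as.integer(n1[keep][ord]), n2 = as.integer(n2[keep][ord]))
}

# Internal: vectorized census of connected 3-node induced subgraphs.
# A 3-node set is weakly connected iff at least two of its three undirected
# node pairs are linked.
triad_census <- function(web) {
  n <- web$n_species
  A <- web$adjacency
  cmb <- combn(n, 3)
  i <- cmb[1, ]; j <- cmb[2, ]; k <- cmb[3, ]
  # A[x, y]: y consumes x (edge x -> y)
  eij <- A[cbind(i, j)]; eji <- A[cbind(j, i)]
  eik <- A[cbind(i, k)]; eki <- A[cbind(k, i)]
  ejk <- A[cbind(j, k)]; ekj <- A[cbind(k, j)]
  uij <- eij | eji; uik <- eik | eki; ujk <- ejk | ekj
  connected <- (uij + uik + ujk) >= 2L
  nl <- eij + eji + eik + eki + ejk + ekj
  # within-triad prey counts (as consumer) and predator counts (as prey)
  prey_i <- eji + eki; prey_j <- eij + ekj; prey_k <- eik + ejk
  pred_i <- eij + eik; pred_j <- eji + ejk; pred_k <- eki + ekj
  cls <- rep("OTHER3", length(i))
  two <- nl == 2L
  cls[two & pmax(prey_i, prey_j, prey_k) == 2L] <- "AC"
  cls[two & pmax(pred_i, pred_j, pred_k) == 2L] <- "EC"
  cls[two & cls == "OTHER3"] <- "TTC"
  list(
    n1 = i[connected], n2 = j[connected], n3 = k[connected],
    class = cls[connected]
  )
}

#' Enumerate predator-prey link instances
#'
#' One instance per trophic link (a mutual-predation pair collapses to a
#' single 2-node instance), nodes in ascending order.
#'
#' @param web a [web_topology()].
#' @return A tibble with `motif_class` (`"PP"`), `n1`, `n2`, and a `nodes`
#'   label column.
#' @export
enumerate_links <- function(web) {
  validate_web_topology(web)
  lc <- link_census(web)
  tibble::tibble(
    motif_class = rep("PP", length(lc$n1)),
    n1 = lc$n1, n2 = lc$n2, n3 = NA_integer_,
    nodes = paste(lc$n1, lc$n2, sep = "-")
  )
}

#' Enumerate connected three-node subgraphs
#'
#' All 3-node subsets whose induced trophic subgraph is weakly connected,
#' classified on the induced link set: apparent competition (`AC`, one
#' predator with two prey), exploitative competition (`EC`, two consumers of
#' one prey), tritrophic chain (`TTC`), and `OTHER3` for every other
#' connected induced pattern, such as omnivory.
#'
#' @param web a [web_topology()].
#' @return A tibble with `motif_class`, `n1 < n2 < n3`, and a `nodes` label.
#' @export
enumerate_triads <- function(web) {
  validate_web_topology(web)
  tc <- triad_census(web)
  tibble::tibble(
    motif_class = tc$class,
    n1 = tc$n1, n2 = tc$n2, n3 = tc$n3,
    nodes = paste(tc$n1, tc$n2, tc$n3, sep = "-")
  )
}

#' Enumerate connected k-node subgraphs
#'
#' Generic enumerator for weakly connected induced subgraphs of `k` nodes
#' (exhaustive; intended for `k <= 4` at 15 species). Instances are not
#' classified beyond size.
#'
#' @param web a [web_topology()].
#' @param k subgraph size (>= 2).
#' @return A tibble with a `nodes` list-column of ascending index vectors.
#' @export
enumerate_subgraphs <- function(web, k) {
  validate_web_topology(web)
  if (k < 2 || k > web$n_species) abort("`k` must be in [2, n_species].")
  U <- web$adjacency | t(web$adjacency)
  cmb <- combn(web$n_species, k)
  keep <- apply(cmb, 2, function(nodes) {
    g <- igraph::graph_from_adjacency_matrix(
      U[nodes, nodes, drop = FALSE], mode = "undirected"
    )
    igraph::components(g)$no == 1L
  })
  tibble::tibble(
    nodes = purrr::map(which(keep), ~ as.integer(cmb[, .x])),
    size = k
  )
}

# Internal fast scan used by the ensembles: returns per-class best instance
# (reactivity, node label) plus the system reactivity. `tri` is a
# triad_census() result, `lk` a link_census() result.
fast_scan <- function(J, lk, tri) {
  S <- symmetric_part(J)
  r_sys <- eigen(S, symmetric = TRUE, only.values = TRUE)$values[1]
  out <- list(system_r = r_sys)
  d <- diag(S)
  r_link <- sym_top_eig2(d[lk$n1], d[lk$n2], S[cbind(lk$n1, lk$n2)])
  best <- which.max(r_link) # census is lex-ordered: first max = lex tie-break
  out$PP <- list(r = r_link[best], nodes = paste(lk$n1[best], lk$n2[best], sep = "-"))
  r_tri <- sym_top_eig3(
    d[tri$n1], d[tri$n2], d[tri$n3],
    S[cbind(tri$n1, tri$n2)], S[cbind(tri$n1, tri$n3)], S[cbind(tri$n2, tri$n3)]
  )
  for (cl in c("AC", "EC", "TTC", "OTHER3")) {
    sel <- tri$class == cl
    if (!any(sel)) {
      out[[cl]] <- list(r = NA_real_, nodes = NA_character_)
      next
    }
    idx <- which(sel)[which.max(r_tri[sel])]
    out[[cl]] <- list(
      r = r_tri[idx],
      nodes = paste(tri$n1[idx], tri$n2[idx], tri$n3[idx], sep = "-")
    )
  }
  if (length(r_tri)) {
    idx <- which.max(r_tri)
    out$ANY3 <- list(
      r = r_tri[idx],
      nodes = paste(tri$n1[idx], tri$n2[idx], tri$n3[idx], sep = "-")
    )
  } else {
    out$ANY3 <- list(r = NA_real_, nodes = NA_character_)
  }
  out
}

#' Scan a Jacobian for motif reactivities
#'
#' Computes, for every enumerated motif instance, the reactivity of its
#' principal submatrix of `S = (J + J')/2` and its share of the system
#' reactivity. By eigenvalue interlacing every share is at most 1.
#'
#' When `web` is supplied, instances are the web's trophic links and
#' connected triads. Without a topology (a bare Jacobian, e.g. read with
#' [read_jacobian()]), every 2- and 3-node subset is scanned and classes are
#' reported as `PAIR`/`TRIPLE`.
#'
#' @param J square numeric Jacobian.
#' @param web optional [web_topology()] matching `J`.
#' @return A tibble with `motif_class`, `nodes`, `reactivity`, `fraction`,
#'   sorted by decreasing fraction, with the system reactivity in attribute
#'   `system_r`.
#' @examples
#' set.seed(1)
#' rea <- sample_stable_reactive(n = 8)
#' scan_motifs(rea$J, rea$web)
#' @export
scan_motifs <- function(J, web = NULL) {
  check_square(J)
  check_finite(J)
  r_sys <- reactivity(J)$r
  if (!is.null(web)) {
    validate_web_topology(web)
    if (web$n_species != nrow(J)) abort("`web` and `J` dimensions differ.")
    inst <- dplyr::bind_rows(enumerate_links(web), enumerate_triads(web))
    node_sets <- purrr::pmap(
      list(inst$n1, inst$n2, inst$n3),
      function(a, b, c) as.integer(stats::na.omit(c(a, b, c)))
    )
  } else {
    n <- nrow(J)
    pairs <- combn(n, 2)
    triples <- if (n >= 3) combn(n, 3) else matrix(integer(), 3, 0)
    node_sets <- c(
      purrr::map(seq_len(ncol(pairs)), ~ pairs[, .x]),
      purrr::map(seq_len(ncol(triples)), ~ triples[, .x])
    )
    inst <- tibble::tibble(
      motif_class = rep(c("PAIR", "TRIPLE"), c(ncol(pairs), ncol(triples))),
      nodes = purrr::map_chr(node_sets, paste, collapse = "-")
    )
  }
  S <- symmetric_part(J)
  inst$reactivity <- purrr::map_dbl(node_sets, function(nd) {
    sym_top_eig(S[nd, nd, drop = FALSE])
  })
  inst$fraction <- inst$reactivity / r_sys
  out <- inst |>
    dplyr::select(dplyr::any_of(c("motif_class", "nodes", "reactivity", "fraction"))) |>
    dplyr::arrange(dplyr::desc(.data$fraction))
  attr(out, "system_r") <- r_sys
  out
}

#' Most reactive motif instance
#'
#' Picks, from a scan table, the instance with the largest reactivity
#' (optionally within one motif class), breaking exact ties by the
#' lexicographically smallest node tuple. Requires a reactive system
#' (positive system reactivity), since the fraction is only meaningful then.
#'
#' @param J square numeric Jacobian.
#' @param instances a tibble from [scan_motifs()] or the enumerators; if it
#'   lacks reactivities they are computed.
#' @param motif_class optional class filter (e.g. `"AC"`).
#' @return A one-row tibble (`motif_class`, `nodes`, `reactivity`,
#'   `fraction`); zero rows if no instance matches the filter.
#' @export
most_reactive_instance <- function(J, instances, motif_class = NULL) {
  r_sys <- reactivity(J)$r
  if (r_sys <= 0) {
    abort("System reactivity is not positive; motif fractions are undefined.")
  }
  if (!is.null(motif_class)) {
    instances <- dplyr::filter(instances, .data$motif_class %in% !!motif_class)
  }
  if (nrow(instances) == 0) {
    return(tibble::tibble(
      motif_class = character(), nodes = character(),
      reactivity = double(), fraction = double()
    ))
  }
  if (!"reactivity" %in% names(instances)) {
    S <- symmetric_part(J)
    node_sets <- strsplit(instances$nodes, "-", fixed = TRUE)
    instances$reactivity <- purrr::map_dbl(node_sets, function(nd) {
      sym_top_eig(S[as.integer(nd), as.integer(nd), drop = FALSE])
    })
  }
  lex_key <- purrr::map_chr(strsplit(instances$nodes, "-", fixed = TRUE), function(nd) {
    paste(sprintf("%05d", as.integer(nd)), collapse = "-")
  })
  instances |>
    dplyr::mutate(fraction = .data$reactivity / r_sys, .lex = lex_key) |>
    dplyr::arrange(dplyr::desc(.data$reactivity), .data$.lex) |>
    dplyr::slice(1) |>
    dplyr::select(dplyr::any_of(c("motif_class", "nodes", "reactivity", "fraction")))
}

#' Node participation in winning motif instances
#'
#' Given ensemble records from a fixed topology, the per-node probability of
#' belonging to the most reactive instance of a motif class across
#' realizations. Probabilities are per node (a triad contributes to three
#' nodes), so they do not sum to 1.
#'
#' @param records an ensemble record tibble ([run_set2()]).
#' @param motif_class which class's winners to tally (default `"AC"`).
#' @param n_species number of species (inferred from records if present).
#' @return A tibble `node`, `participation` sorted by node.
#' @export
node_participation <- function(records, motif_class = "AC", n_species = NULL) {
  if (nrow(records) == 0) abort("`records` is empty.")
  if (length(unique(records$topology_hash)) != 1L) {
    abort("Node participation requires records from a single fixed topology.")
  }
  col <- paste0("best_nodes_", motif_class)
  if (!col %in% names(records)) {
    abort(sprintf("No column `%s` in records.", col))
  }
  n_species <- n_species %||% records$n_species[1]
  winners <- records[[col]]
  winners <- winners[!is.na(winners)]
  if (length(winners) == 0) abort("No winning instances for this class.")
  counts <- table(factor(
    unlist(strsplit(winners, "-", fixed = TRUE)),
    levels = as.character(seq_len(n_species))
  ))
  tibble::tibble(
    node = seq_len(n_species),
    participation = as.double(counts) / length(winners)
  )
}
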