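#' Food-web topology objects
#'
#' A `web_topology` is a directed trophic graph: `n_species`, a vector of
#' per-species niche values in `[0, 1]`, and a boolean adjacency matrix with
#' `adjacency[i, j] == TRUE` iff species `j` consumes species `i`
#' (prey-to-predator orientation, used consistently throughout the package).
#'
#' Every valid topology is connected as an undirected graph, has at least one
#' basal species (a species with no prey), pairwise-distinct niche values, and
#' no self-loops.
#'
#' @param n_species number of species.
#' @param niche_values numeric vector of length `n_species`, values in `[0, 1]`.
#' @param adjacency `n_species x n_species` logical matrix, prey in rows,
#'   predators in columns.
#' @param labels optional character vector of species identifiers.
#'
#' @return A `web_topology` object.
#' @seealso [niche_web()], [trophic_roles()], [read_topology()]
#' @export
web_topology <- function(n_species, niche_values, adjacency, labels = NULL) {
  adjacency <- matrix(as.logical(adjacency), n_species, n_species)
  web <- structure(
    list(
      n_species = as.integer(n_species),
      niche_values = as.double(niche_values),
      adjacency = adjacency,
      labels = labels %||% paste0("sp", seq_len(n_species))
    ),
    class = "web_topology"
  )
  validate_web_topology(web)
  web
}

validate_web_topology <- function(web) {
  n <- web$n_species
  if (n < 2L) abort("A web needs at least 2 species.")
  if (length(web$niche_values) != n) {
    abort("`niche_values` must have one entry per species.")
  }
  if (any(web$niche_values < 0 | web$niche_values > 1)) {
    abort("Niche values must lie in [0, 1].")
  }
  if (anyDuplicated(web$niche_values)) abort("Niche values must be distinct.")
  if (!identical(dim(web$adjacency), c(n, n))) {
    abort("`adjacency` must be n_species x n_species.")
  }
  if (any(diag(web$adjacency))) abort("Self-loops (cannibalism) are not allowed.")
  if (!web_is_connected(web)) abort("The web must be a single connected component.")
  if (!any(basal_species(web))) abort("At least one basal species is required.")
  invisible(web)
}

web_is_connected <- function(web) {
  u <- web$adjacency | t(web$adjacency)
  g <- igraph::graph_from_adjacency_matrix(u, mode = "undirected")
  igraph::components(g)$no == 1L
}

basal_species <- function(web) colSums(web$adjacency) == 0L

# Internal: raw niche-model draw, before invariant filtering. Consumes
# 4 * n uniforms (niche values, range fractions, centres) per call.
# n_raw_links counts the links produced by the niche rule itself, including
# cannibalistic self-links (for which E[links] = C n^2 holds exactly);
# deleting the diagonal and filtering invalid webs both bias realized
# connectance, which the calibration tests measure.
niche_web_draw <- function(n, connectance) {
  beta_shape <- 1 / (2 * connectance) - 1
  nv <- runif(n)
  range_frac <- rbeta(n, 1, beta_shape)
  r <- range_frac * nv
  centre <- runif(n, r / 2, pmin(nv, 1 - r / 2))
  adj <- matrix(FALSE, n, n)
  for (j in seq_len(n)) {
    adj[, j] <- nv >= centre[j] - r[j] / 2 & nv <= centre[j] + r[j] / 2
  }
  n_raw <- sum(adj)
  diag(adj) <- FALSE # cannibalistic links deleted, not resampled
  list(niche_values = nv, adjacency = adj, n_raw_links = n_raw)
}

#' Generate a niche-model food web
#'
#' Draws a topology from the niche model: each species gets a niche value
#' `n_i ~ U(0, 1)`, a feeding range `r_i = x n_i` with
#' `x ~ Beta(1, 1/(2C) - 1)` so that the expected connectance is `C`, and a
#' range centre `c_i ~ U(r_i / 2, min(n_i, 1 - r_i / 2))`; species `j` consumes
#' every species whose niche value falls inside `[c_j - r_j/2, c_j + r_j/2]`.
#'
#' Raw draws violating the [web_topology()] invariants (disconnected webs,
#' webs without a basal species, duplicate niche values) are discarded and
#' redrawn from the same random stream. Self-loops produced by the niche rule
#' are deleted. Accepted webs are re-indexed in ascending niche-value order so
#' that species identity is reproducible.
#'
#' Uses the session RNG; call `set.seed()` beforehand for reproducibility.
#'
#' @param n number of species (at least 2).
#' @param connectance target connectance `C = L / n^2`, in `(0, 0.5)`.
#'   Default 0.15, a central value for published 15-species niche webs.
#' @param max_tries retry budget for the rejection loop.
#'
#' @return A [web_topology()].
#' @examples
#' set.seed(1)
#' web <- niche_web(15)
#' trophic_roles(web)
#' @export
niche_web <- function(n = 15, connectance = 0.15, max_tries = 1e4) {
  if (n < 2) abort("`n` must be at least 2.")
  if (connectance <= 0 || connectance >= 0.5) {
    abort("`connectance` must lie in (0, 0.5): the Beta shape 1/(2C) - 1 must be positive.")
  }
  for (i in seq_len(max_tries)) {
    raw <- niche_web_draw(n, connectance)
    if (anyDuplicated(raw$niche_values)) next
    ord <- order(raw$niche_values)
    web <- structure(
      list(
        n_species = as.integer(n),
        niche_values = raw$niche_values[ord],
        adjacency = raw$adjacency[ord, ord, drop = FALSE],
        labels = paste0("sp", seq_len(n))
      ),
      class = "web_topology"
    )
    if (!web_is_connected(web)) next
    if (!any(basal_species(web))) next
    return(web)
  }
  abort(sprintf("No valid niche web found in %d tries (n = %d, C = %g).",
                max_tries, n, connectance))
}

#' Trophic roles and neighbourhoods
#'
#' Classifies each species as basal (no prey) or consumer and lists its prey
#' and predator sets.
#'
#' @param web a [web_topology()].
#' @return A tibble with one row per species: `species`, `label`, `niche`,
#'   `role`, `n_prey`, `n_predators`, and list-columns `prey` and `predators`
#'   of species indices.
#' @export
trophic_roles <- function(web) {
  validate_web_topology(web)
  n <- web$n_species
  prey <- purrr::map(seq_len(n), ~ which(web$adjacency[, .x]))
  predators <- purrr::map(seq_len(n), ~ which(web$adjacency[.x, ]))
  tibble::tibble(
    species = seq_len(n),
    label = web$labels,
    niche = web$niche_values,
    role = ifelse(lengths(prey) == 0L, "basal", "consumer"),
    n_prey = lengths(prey),
    n_predators = lengths(predators),
    prey = prey,
    predators = predators
  )
}

#' Number of trophic links in a web
#' @param web a [web_topology()].
#' @return Integer link count.
#' @export
n_links <- function(web) sum(web$adjacency)

#' @export
print.web_topology <- function(x, ...) {
  cat(sprintf(
    "<web_topology> %d species, %d links (connectance %.3f), %d basal\n",
    x$n_species, n_links(x), n_links(x) / x$n_species^2, sum(basal_species(x))
  ))
  invisible(x)
}

#' @method as_tibble web_topology
#' @export
as_tibble.web_topology <- function(x, ...) {
  e <- which(x$adjacency, arr.ind = TRUE)
  tibble::tibble(prey = as.integer(e[, 1]), predator = as.integer(e[, 2])) |>
    dplyr::arrange(.data$prey, .data$predator)
}

#' Read and write food-web topologies
#'
#' Two plain-text formats are supported. A tab-separated edge list holds
#' `prey<TAB>predator` pairs of 0-based integer indices, lines starting with
#' `#` ignored; since edge lists carry no niche values, synthetic evenly
#' spaced values `(i - 0.5) / n` are assigned in index order. A JSON document
#' `{n_species, niche_values, edges}` round-trips niche values at 17
#' significant digits, so `read_topology(write_topology(web, path))`
#' reproduces the web bit-exactly.
#'
#' @param path file path; format chosen by extension (`.json` vs anything else).
#' @param web a [web_topology()].
#' @return `read_topology()` returns a [web_topology()]; `write_topology()`
#'   returns `path` invisibly.
#' @export
read_topology <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    n <- as.integer(doc$n_species)
    if (is.null(n) || is.na(n) || n < 2) abort("JSON topology: invalid `n_species`.")
    edges <- matrix(as.integer(doc$edges), ncol = 2)
    adj <- edges_to_adjacency(edges, n, path)
    return(web_topology(n, as.double(doc$niche_values), adj))
  }
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) abort(sprintf("'%s': no edges found (empty file).", path))
  rows <- which(keep)
  edges <- matrix(NA_integer_, length(rows), 2)
  for (q in seq_along(rows)) {
    parts <- strsplit(trimws(lines[rows[q]]), "[\t ]+")[[1]]
    vals <- suppressWarnings(as.integer(parts))
    if (length(vals) != 2 || anyNA(vals)) {
      abort(sprintf("'%s' line %d: expected 'prey<TAB>predator' integers, got '%s'.",
                    path, rows[q], lines[rows[q]]))
    }
    if (vals[1] == vals[2]) {
      abort(sprintf("'%s' line %d: self-loop '%d %d' is not allowed.",
                    path, rows[q], vals[1], vals[2]))
    }
    edges[q, ] <- vals + 1L # file is 0-based
  }
  n <- max(edges)
  adj <- edges_to_adjacency(edges, n, path)
  web_topology(n, (seq_len(n) - 0.5) / n, adj)
}

edges_to_adjacency <- function(edges, n, path) {
  if (any(edges < 1L) || any(edges > n)) {
    abort(sprintf("'%s': edge index out of range [0, %d].", path, n - 1L))
  }
  if (any(edges[, 1] == edges[, 2])) {
    abort(sprintf("'%s': self-loops are not allowed.", path))
  }
  adj <- matrix(FALSE, n, n)
  adj[edges] <- TRUE
  adj
}

#' @rdname read_topology
#' @export
write_topology <- function(web, path) {
  validate_web_topology(web)
  e <- which(web$adjacency, arr.ind = TRUE)
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    # niche values as 17-significant-digit decimal text: exact double round trip
    writeLines(paste0(
      '{"n_species": ', web$n_species,
      ', "niche_values": [',
      paste(sprintf("%.17g", web$niche_values), collapse = ", "),
      '], "edges": [',
      paste(sprintf("[%d, %d]", e[, 1], e[, 2]), collapse = ", "),
      "]}"
    ), path)
  } else {
    writeLines(
      c("# prey\tpredator (0-based)",
        sprintf("%d\t%d", e[, 1] - 1L, e[, 2] - 1L)),
      path
    )
  }
  invisible(path)
}
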