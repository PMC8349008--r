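# Shared fixtures and independent oracles used across the suite.

# quick claims-row constructor with sensible defaults
claim_rows <- function(patient_id, provider_id = "P1",
                       service_date = as.Date("2016-03-01"),
                       claim_type = "outpatient",
                       procedure_code = "99213",
                       payer = "medicaid",
                       dx1 = "F32.9", dx2 = "") {
  tibble::tibble(patient_id = patient_id, provider_id = provider_id,
                 service_date = as.Date(service_date),
                 claim_type = claim_type, procedure_code = procedure_code,
                 payer = payer, dx1 = dx1, dx2 = dx2)
}

patient_rows <- function(patient_id, birth_year = 1980L,
                         sex = "female") {
  tibble::tibble(patient_id = patient_id,
                 birth_year = as.integer(birth_year), sex = sex)
}

provider_rows <- function(provider_id, specialty_group = "pcp") {
  tibble::tibble(provider_id = provider_id,
                 taxonomy_code = "",
                 specialty_group = specialty_group)
}

# named undirected graph from a two-column character edge matrix
named_graph <- function(edges, vertices = NULL) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]),
    directed = FALSE,
    vertices = vertices %||% sort(unique(as.vector(edges))))
  igraph::V(g)$specialty_group <- igraph::V(g)$specialty_group %||%
    rep("pcp", igraph::vcount(g))
  g
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# --- independent oracles ---------------------------------------------------

# breadth-first-search connected components, written against the adjacency
# list only (independent of igraph's components())
bfs_components <- function(g) {
  vn <- igraph::V(g)$name
  adj <- igraph::as_adj_list(g, mode = "all")
  n <- length(vn)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      for (w in as.integer(adj[[v]])) {
        if (is.na(comp[w])) {
          comp[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  stats::setNames(comp, vn)
}

# the largest-component vertex set under the same tie rule the package
# documents (largest size, then smallest member name)
bfs_largest_component <- function(g) {
  comp <- bfs_components(g)
  sizes <- table(comp)
  big <- names(sizes)[sizes == max(sizes)]
  firsts <- vapply(big, function(ci) min(names(comp)[comp == ci]),
                   character(1))
  chosen <- big[order(firsts)[1]]
  sort(names(comp)[comp == chosen])
}

# pair-counting continuity oracle: fraction of ordered visit pairs that are
# with the same provider, enumerated by brute force
coc_pair_oracle <- function(provider_of_visit) {
  n <- length(provider_of_visit)
  stopifnot(n >= 2)
  same <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && provider_of_visit[i] == provider_of_visit[j]) {
        same <- same + 1L
      }
    }
  }
  same / (n * (n - 1))
}

# visit records for one synthetic patient-year given per-provider counts
visits_from_counts <- function(counts, patient = "M1", year = 2016L) {
  prov <- rep(sprintf("P%02d", seq_along(counts)), counts)
  tibble::tibble(
    patient_id = patient,
    provider_id = prov,
    service_date = as.Date(sprintf("%d-01-01", year)) +
      seq_along(prov) - 1,
    year = year)
}

# definitional modularity written from scratch (not via the package or
# igraph): Q = sum_c [ e_c/m - (d_c/(2m))^2 ]
modularity_oracle <- function(g, membership) {
  vn <- igraph::V(g)$name
  memb <- membership[vn]
  el <- igraph::as_edgelist(g)
  m <- nrow(el)
  q <- 0
  for (cc in unique(memb)) {
    inside <- vn[memb == cc]
    e_c <- sum(el[, 1] %in% inside & el[, 2] %in% inside)
    d_c <- sum(el[, 1] %in% inside) + sum(el[, 2] %in% inside)
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# replay a merge history and assert every chosen delta-Q is maximal over all
# connected community pairs (exhaustive scan per step); returns TRUE/error
check_greedy_maximality <- function(g, history, tol = 1e-12) {
  vn <- igraph::V(g)$name
  memb <- stats::setNames(vn, vn)   # community id = smallest member name
  el <- igraph::as_edgelist(g)
  m <- nrow(el)
  deg <- igraph::degree(g)
  for (s in seq_len(nrow(history))) {
    # all connected community pairs and their delta-Q, from scratch
    ca <- memb[el[, 1]]
    cb <- memb[el[, 2]]
    cross <- ca != cb
    pairs <- unique(data.frame(
      a = pmin(ca[cross], cb[cross]),
      b = pmax(ca[cross], cb[cross])))
    dqs <- vapply(seq_len(nrow(pairs)), function(k) {
      ia <- pairs$a[k]; ib <- pairs$b[k]
      between <- sum((ca == ia & cb == ib) | (ca == ib & cb == ia))
      aa <- sum(deg[memb == ia]) / (2 * m)
      ab <- sum(deg[memb == ib]) / (2 * m)
      2 * (between / (2 * m) - aa * ab)
    }, numeric(1))
    chosen <- history$delta_q[s]
    if (chosen < max(dqs) - tol) {
      stop(sprintf("step %d: chosen dQ %.15f < max %.15f", s, chosen,
                   max(dqs)))
    }
    # apply the merge
    ia <- history$community_a[s]; ib <- history$community_b[s]
    memb[memb == ib] <- ia
  }
  TRUE
}

# random provider graph with vertex names
random_named_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("r%04d", seq_len(n))
  g
}
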