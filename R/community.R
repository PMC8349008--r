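#' Newman modularity of a partition
#'
#' Computes \eqn{Q = \sum_c [ e_c/m - (d_c/2m)^2 ]} over communities
#' \eqn{c}, where \eqn{m} is the number of edges, \eqn{e_c} the number of
#' edges with both endpoints in \eqn{c}, and \eqn{d_c} the total degree of
#' \eqn{c}. Q is the chance-corrected fraction of edges falling within
#' communities rather than between them.
#'
#' @param graph an undirected `igraph`.
#' @param membership community labels: a vector named by vertex name, or in
#'   vertex order; any atomic label type.
#' @return a single number in \eqn{[-0.5, 1]}.
#' @export
graph_modularity <- function(graph, membership) {
  m <- igraph::ecount(graph)
  if (m == 0) stop("modularity is undefined for an edgeless graph")
  vn <- igraph::V(graph)$name
  if (!is.null(names(membership))) {
    membership <- membership[vn]
  }
  stopifnot(length(membership) == igraph::vcount(graph),
            !anyNA(membership))
  lab <- as.character(membership)
  ends <- igraph::ends(graph, igraph::E(graph), names = TRUE)
  c1 <- lab[match(ends[, 1], vn)]
  c2 <- lab[match(ends[, 2], vn)]
  within <- tapply(c1 == c2, c1, sum)
  e_c <- rep(0, length(unique(lab)))
  names(e_c) <- unique(lab)
  # edges counted within the community of their first endpoint only when
  # both endpoints agree; accumulate properly over both orientations
  e_tab <- table(factor(c1[c1 == c2], levels = names(e_c)))
  e_c[names(e_tab)] <- as.numeric(e_tab)
  deg <- igraph::degree(graph)
  d_c <- tapply(deg, factor(lab, levels = names(e_c)), sum)
  d_c[is.na(d_c)] <- 0
  sum(e_c / m - (d_c / (2 * m))^2)
}

#' Fast-greedy (CNM) modularity-maximizing community detection
#'
#' Agglomerative community detection in the style of Clauset, Newman and
#' Moore: starting from singleton communities, repeatedly merge the pair of
#' *connected* communities with the largest modularity gain \eqn{\Delta Q},
#' and return the partition at the peak of the modularity trajectory. The
#' algorithm chooses both the number of communities and the unique assignment
#' of every vertex.
#'
#' Determinism: \eqn{\Delta Q} ties are broken toward the lexicographically
#' smallest (community_a, community_b) pair, where a community's id is the
#' smallest vertex name among its members. Identical graphs therefore yield
#' identical partitions regardless of vertex ordering.
#'
#' @param graph an undirected `igraph`; isolated vertices remain singleton
#'   communities, disconnected components are agglomerated independently
#'   (merges never span components).
#' @return an object of class `community_partition`: a list with
#'   `membership` (tibble `provider_id`, `community` with labels `C1`, `C2`,
#'   ... ordered by decreasing size), `modularity` (recomputed from the
#'   definition for the returned partition), `n_communities`,
#'   `merge_history` (tibble `step`, `community_a`, `community_b`,
#'   `delta_q`, `q_after`), and `level = "community"`.
#' @export
fast_greedy_communities <- function(graph) {
  vn <- igraph::V(graph)$name
  n <- length(vn)
  if (n < 2) {
    memb <- tibble::tibble(provider_id = vn,
                           community = rep("C1", n))
    return(new_community_partition(memb, modularity = NA_real_,
                                   merge_history = empty_merge_history(),
                                   level = "community"))
  }
  m <- igraph::ecount(graph)
  if (m == 0) {
    memb <- tibble::tibble(provider_id = sort(vn),
                           community = paste0("C", seq_len(n)))
    return(new_community_partition(memb, modularity = NA_real_,
                                   merge_history = empty_merge_history(),
                                   level = "community"))
  }

  # internal community key = index of the smallest-named member vertex in
  # name-sorted order, so integer comparison == lexicographic id comparison
  ord <- order(vn)
  name_sorted <- vn[ord]
  vkey <- match(vn, name_sorted)            # vertex -> initial key

  deg <- igraph::degree(graph)
  a <- numeric(n)
  a[vkey] <- deg / (2 * m)

  ends <- igraph::ends(graph, igraph::E(graph), names = FALSE)
  ek1 <- vkey[ends[, 1]]
  ek2 <- vkey[ends[, 2]]
  # drop self loops defensively (contract: none)
  keep <- ek1 != ek2
  ek1 <- ek1[keep]; ek2 <- ek2[keep]
  lo <- pmin(ek1, ek2); hi <- pmax(ek1, ek2)

  # w[i,j] = (edges between i and j) / (2m); dq = 2*(w - a_i a_j)
  pkey <- paste(lo, hi, sep = "_")
  wtab <- tapply(rep(1 / (2 * m), length(pkey)), pkey, sum)
  w <- as.numeric(wtab)
  names(w) <- names(wtab)
  split_keys <- strsplit(names(w), "_", fixed = TRUE)
  ki <- as.integer(vapply(split_keys, `[`, "", 1L))
  kj <- as.integer(vapply(split_keys, `[`, "", 2L))
  dq <- 2 * (w - a[ki] * a[kj])
  names(dq) <- names(w)

  # per-community neighbor weight lists
  nb <- vector("list", n)
  for (idx in seq_along(ki)) {
    i <- ki[idx]; j <- kj[idx]; wij <- w[idx]
    nb[[i]][as.character(j)] <- wij
    nb[[j]][as.character(i)] <- wij
  }

  membership <- vkey                    # per vertex (original order)
  q <- -sum(a^2)
  best_q <- q
  best_membership <- membership
  hist_a <- character(0); hist_b <- character(0)
  hist_dq <- numeric(0); hist_q <- numeric(0)

  while (length(dq) > 0) {
    mx <- max(dq)
    cand <- which(dq >= mx - 1e-12)
    if (length(cand) > 1) {
      sk <- strsplit(names(dq)[cand], "_", fixed = TRUE)
      ca <- as.integer(vapply(sk, `[`, "", 1L))
      cb <- as.integer(vapply(sk, `[`, "", 2L))
      cand <- cand[order(ca, cb)[1]]
    }
    key <- names(dq)[cand]
    parts <- as.integer(strsplit(key, "_", fixed = TRUE)[[1]])
    i <- parts[1]; j <- parts[2]          # i < j; merged key = i
    dstar <- dq[[cand]]

    q <- q + dstar
    hist_a <- c(hist_a, name_sorted[i])
    hist_b <- c(hist_b, name_sorted[j])
    hist_dq <- c(hist_dq, dstar)
    hist_q <- c(hist_q, q)

    ni <- nb[[i]]; nj <- nb[[j]]
    # drop stale dq entries touching i or j
    stale <- c(pair_key(i, as.integer(names(ni))),
               pair_key(j, as.integer(names(nj))))
    dq <- dq[!(names(dq) %in% stale)]

    merged <- ni
    for (k in names(nj)) {
      merged[k] <- (if (k %in% names(merged)) merged[[k]] else 0) + nj[[k]]
    }
    merged <- merged[!(names(merged) %in% c(as.character(i),
                                            as.character(j)))]
    a[i] <- a[i] + a[j]
    a[j] <- 0
    nb[[j]] <- NULL_weights()
    nb[[i]] <- merged

    if (length(merged) > 0) {
      ks <- as.integer(names(merged))
      newdq <- 2 * (as.numeric(merged) - a[i] * a[ks])
      names(newdq) <- pair_key(i, ks)
      for (pos in seq_along(ks)) {
        k <- ks[pos]
        nbk <- nb[[k]]
        nbk <- nbk[!(names(nbk) %in% c(as.character(i), as.character(j)))]
        nbk[as.character(i)] <- merged[[pos]]
        nb[[k]] <- nbk
      }
      dq <- c(dq, newdq)
    }

    membership[membership == j] <- i
    if (q > best_q + 1e-12) {
      best_q <- q
      best_membership <- membership
    }
  }

  memb <- label_partition(vn, best_membership, prefix = "C")
  history <- tibble::tibble(step = seq_along(hist_dq),
                            community_a = hist_a,
                            community_b = hist_b,
                            delta_q = hist_dq,
                            q_after = hist_q)
  q_exact <- graph_modularity(graph, setNames(memb$community,
                                              memb$provider_id))
  new_community_partition(memb, modularity = q_exact,
                          merge_history = history, level = "community")
}

NULL_weights <- function() setNames(numeric(0), character(0))

empty_merge_history <- function() {
  tibble::tibble(step = integer(), community_a = character(),
                 community_b = character(), delta_q = numeric(),
                 q_after = numeric())
}

# label communities C1.. (or S1..) by decreasing size, ties by smallest
# member vertex name
label_partition <- function(vn, membership, prefix = "C") {
  df <- tibble::tibble(provider_id = vn, key = membership)
  sizes <- df |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(n = dplyr::n(), first_id = min(.data$provider_id),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$first_id) |>
    dplyr::mutate(label = paste0(prefix, dplyr::row_number()))
  df |>
    dplyr::left_join(dplyr::select(sizes, "key", "label"), by = "key") |>
    dplyr::transmute(provider_id = .data$provider_id,
                     community = .data$label) |>
    dplyr::arrange(.data$provider_id)
}

new_community_partition <- function(membership, modularity, merge_history,
                                    level, parent = NA_character_) {
  structure(
    list(membership = membership,
         modularity = modularity,
         n_communities = length(unique(membership$community)),
         merge_history = merge_history,
         level = level,
         parent = parent),
    class = "community_partition"
  )
}

#' @export
print.community_partition <- function(x, ...) {
  cat("<community_partition> level:", x$level,
      if (!is.na(x$parent)) paste0("(parent ", x$parent, ")"), "\n")
  cat("  vertices:", nrow(x$membership),
      " communities:", x$n_communities,
      " modularity:", format(x$modularity, digits = 4), "\n")
  invisible(x)
}

#' Tidy a community partition
#'
#' @param x a `community_partition`.
#' @param ... unused.
#' @return tibble `provider_id`, `community`.
#' @exportS3Method generics::tidy
tidy.community_partition <- function(x, ...) x$membership

#' One-row summary of a community partition
#'
#' @param x a `community_partition`.
#' @param ... unused.
#' @return tibble with `level`, `n_communities`, `modularity`, `n_vertices`.
#' @exportS3Method generics::glance
glance.community_partition <- function(x, ...) {
  tibble::tibble(level = x$level, n_communities = x$n_communities,
                 modularity = x$modularity,
                 n_vertices = nrow(x$membership))
}

#' Nested sub-community detection
#'
#' For each community with at least `min_size` providers, induces its
#' subgraph and re-runs [fast_greedy_communities()] on it (using the
#' subgraph's own edge count), yielding mutually exclusive sub-communities
#' nested in the parent. Sub-communities smaller than `min_size`, and all of
#' the providers of communities smaller than `min_size`, receive an `NA`
#' sub-community label and are excluded from further analysis.
#'
#' @param graph the provider graph the communities were detected on.
#' @param communities a `community_partition` at community level.
#' @param min_size minimum provider count for a community or sub-community
#'   to be retained (default 10).
#' @return list with `assignments` (tibble `provider_id`, `community`,
#'   `subcommunity` with hierarchical labels `"C2.S3"` or `NA`),
#'   `community_modularity` (tibble `community`, `n_providers`,
#'   `modularity_subcommunities`, `n_subcommunities`), and `partitions`
#'   (named list of per-community `community_partition` objects).
#' @export
nested_subcommunities <- function(graph, communities, min_size = 10L) {
  memb <- communities$membership
  by_comm <- split(memb$provider_id, memb$community)
  comm_order <- names(by_comm)[order(-lengths(by_comm), names(by_comm))]

  parts <- list()
  assign_rows <- list()
  mod_rows <- list()

  for (cm in comm_order) {
    ids <- by_comm[[cm]]
    if (length(ids) < min_size) {
      assign_rows[[cm]] <- tibble::tibble(
        provider_id = ids, community = cm,
        subcommunity = NA_character_)
      next
    }
    sub <- igraph::induced_subgraph(graph, ids)
    part <- fast_greedy_communities(sub)
    part$level <- "subcommunity"
    part$parent <- cm
    sub_memb <- part$membership
    sizes <- table(sub_memb$community)
    keep_labels <- names(sizes)[sizes >= min_size]
    sub_memb <- sub_memb |>
      dplyr::mutate(subcommunity = ifelse(
        .data$community %in% keep_labels,
        paste0(cm, ".", sub("^C", "S", .data$community)),
        NA_character_)) |>
      dplyr::transmute(provider_id = .data$provider_id,
                       community = cm,
                       subcommunity = .data$subcommunity)
    parts[[cm]] <- part
    assign_rows[[cm]] <- sub_memb
    mod_rows[[cm]] <- tibble::tibble(
      community = cm,
      n_providers = length(ids),
      modularity_subcommunities = part$modularity,
      n_subcommunities = length(keep_labels))
  }

  list(
    assignments = dplyr::bind_rows(assign_rows) |>
      dplyr::arrange(.data$provider_id),
    community_modularity = dplyr::bind_rows(mod_rows),
    partitions = parts
  )
}
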