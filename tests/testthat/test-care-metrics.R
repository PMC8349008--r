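test_that("Bice-Boxerman CoC matches hand-evaluated cases", {
  # 4 visits, one provider -> (16-4)/12 = 1
  r1 <- patient_coc(visits_from_counts(c(4)))
  expect_equal(r1$coc, 1)
  expect_equal(r1$p, 1)
  # 4 visits, 4 providers -> 0
  expect_equal(patient_coc(visits_from_counts(c(1, 1, 1, 1)))$coc, 0)
  # n_i = (3,2,1): (9+4+1-6)/30
  expect_equal(patient_coc(visits_from_counts(c(3, 2, 1)))$coc,
               (9 + 4 + 1 - 6) / 30)
  # under four visits -> ineligible
  r4 <- patient_coc(visits_from_counts(c(2, 1)))
  expect_false(r4$eligible)
  expect_true(is.na(r4$coc))
  # years are kept separate
  two_years <- dplyr::bind_rows(
    visits_from_counts(c(4), year = 2016L),
    visits_from_counts(c(2, 2), year = 2017L))
  r5 <- patient_coc(two_years)
  expect_equal(nrow(r5), 2)
  expect_equal(r5$coc[r5$year == 2016], 1)
  expect_equal(r5$coc[r5$year == 2017], (4 + 4 - 4) / 12)
})

test_that("CoC equals the pair-counting oracle on random visit multisets", {
  set.seed(8)
  for (rep in 1:200) {
    counts <- table(sample(1:6, sample(4:15, 1), TRUE))
    v <- visits_from_counts(as.integer(counts))
    got <- patient_coc(v)$coc
    oracle <- coc_pair_oracle(rep(seq_along(counts), counts))
    expect_equal(got, oracle, tolerance = 1e-12)
    expect_gte(got, 0)
    expect_lte(got, 1)
  }
})

test_that("CoC increases when visits concentrate (majorization spot check)", {
  # moving one visit from provider 2 onto provider 1 raises CoC
  expect_gt(patient_coc(visits_from_counts(c(4, 1)))$coc,
            patient_coc(visits_from_counts(c(3, 2)))$coc)
  expect_gt(patient_coc(visits_from_counts(c(5, 1, 1)))$coc,
            patient_coc(visits_from_counts(c(4, 2, 1)))$coc)
})

test_that("provider mean CoC pools eligible patient-years only", {
  v <- dplyr::bind_rows(
    visits_from_counts(c(2, 2), patient = "M1"),        # coc 1/3, P01 P02
    visits_from_counts(c(4), patient = "M2"),           # coc 1, P01
    visits_from_counts(c(2, 1), patient = "M3"))        # ineligible
  coc <- patient_coc(v)
  got <- provider_mean_coc(v, coc)
  # P01 appears in M1 (1/3) and M2 (1): mean 2/3
  expect_equal(got$mean_coc[got$provider_id == "P01"], (1 / 3 + 1) / 2)
  # P02 appears in M1 only
  expect_equal(got$mean_coc[got$provider_id == "P02"], 1 / 3)
  # a provider seen only by ineligible patient-years is absent (missing)
  expect_false("P03" %in% got$provider_id)
})

test_that("alter mean CoC averages neighbors and skips missing", {
  g <- named_graph(cbind(c("a", "a", "a", "x"),
                         c("b", "c", "d", "y")))
  profiles <- tibble::tibble(
    provider_id = c("a", "b", "c", "d", "x", "y"),
    mean_coc = c(0.9, 0.2, 0.4, NA, 0.3, NA))
  got <- alter_mean_coc(g, profiles)
  al <- stats::setNames(got$alter_mean_coc, got$provider_id)
  expect_equal(al[["a"]], 0.3)          # mean(0.2, 0.4), NA skipped
  expect_equal(al[["b"]], 0.9)          # single neighbor
  expect_true(is.na(al[["x"]]))         # only neighbor y has missing CoC
  expect_equal(al[["y"]], 0.3)
  # isolated vertex -> missing
  g_iso <- named_graph(cbind("a", "b"), vertices = c("a", "b", "z"))
  got_iso <- alter_mean_coc(g_iso, tibble::tibble(
    provider_id = c("a", "b", "z"), mean_coc = c(0.1, 0.2, 0.3)))
  expect_true(is.na(got_iso$alter_mean_coc[got_iso$provider_id == "z"]))
})

test_that("local transitivity matches direct pair counts", {
  # triangle: all 1
  tri <- named_graph(cbind(c("a", "b", "c"), c("b", "c", "a")))
  expect_equal(local_transitivity(tri)$transitivity, rep(1, 3))
  # 5-star center: 0; leaves degree 1 -> NA
  star <- named_graph(cbind(rep("hub", 5), paste0("leaf", 1:5)))
  lt <- local_transitivity(star)
  expect_equal(lt$transitivity[lt$provider_id == "hub"], 0)
  expect_true(all(is.na(lt$transitivity[lt$provider_id != "hub"])))
  # v with neighbors {a,b,c}, only edge ab present -> 1/3
  g <- named_graph(cbind(c("v", "v", "v", "a"), c("a", "b", "c", "b")))
  lt2 <- local_transitivity(g)
  expect_equal(lt2$transitivity[lt2$provider_id == "v"], 1 / 3)
  # clique mean 1; tree all 0/NA
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  expect_equal(mean(local_transitivity(k5)$transitivity), 1)
  tree <- named_graph(cbind(c("r", "r", "b"), c("a", "b", "c")))
  tt <- local_transitivity(tree)$transitivity
  expect_true(all(tt[!is.na(tt)] == 0))
})

test_that("degree sums to twice the edge count", {
  for (s in 1:5) {
    g <- random_named_graph(40, 0.1, seed = 400 + s)
    expect_equal(sum(local_transitivity(g)$degree),
                 2 * igraph::ecount(g))
  }
})

# Crafted 8-vertex fixture with known labels; hand-computed expectations.
# Graph: community K = {k1 pcp, k2 pcp, k3 psy, k4 bhs} (clique minus k3-k4)
#        community L = {l1 pcp, l2 bhs, l3 bhs, l4 psy} (path l1-l2-l3-l4
#        plus edge l1-l3); bridge k4-l1.
fixture_graph <- function() {
  edges <- cbind(
    c("k1", "k1", "k1", "k2", "k2", "l1", "l2", "l3", "l1", "k4"),
    c("k2", "k3", "k4", "k3", "k4", "l2", "l3", "l4", "l3", "l1"))
  verts <- data.frame(
    name = c("k1", "k2", "k3", "k4", "l1", "l2", "l3", "l4"),
    specialty_group = c("pcp", "pcp", "psychiatrist", "bh_specialist",
                        "pcp", "bh_specialist", "bh_specialist",
                        "psychiatrist"))
  igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]),
    directed = FALSE, vertices = verts)
}

test_that("structural profile matches a hand-computed fixture", {
  g <- fixture_graph()
  assignments <- tibble::tibble(
    provider_id = c("k1", "k2", "k3", "k4", "l1", "l2", "l3", "l4"),
    community = rep(c("C1", "C2"), each = 4),
    subcommunity = rep(c("C1.S1", "C2.S1"), each = 4))
  # one patient per provider pair that shares, plus visit history for CoC
  claims <- dplyr::bind_rows(
    claim_rows(rep("M1", 2), provider_id = c("k1", "k2")),
    claim_rows(rep("M2", 2), provider_id = c("k3", "k4")),
    claim_rows(rep("M3", 2), provider_id = c("l1", "k1")))
  visits <- dplyr::bind_rows(
    visits_from_counts(c(3, 1), patient = "M1"),   # P01,P02 -> map below
    visits_from_counts(c(4), patient = "M2"))
  # remap synthetic provider codes onto fixture ids
  visits$provider_id <- c("k1", "k1", "k1", "k2", "k3", "k3", "k3", "k3")
  coc <- patient_coc(visits)
  prof <- structural_profile(g, assignments, claims, visits, coc)
  rowk1 <- prof[prof$provider_id == "k1", ]
  # k1 neighbors: k2 (pcp), k3, k4 -> degree 3, pcp degree 1 (same comm)
  expect_equal(rowk1$degree, 3L)
  expect_equal(rowk1$degree_to_pcp, 1L)
  expect_equal(rowk1$degree_to_pcp_same_community, 1L)
  expect_equal(rowk1$degree_to_pcp_same_subcommunity, 1L)
  # k1 neighbor pairs: (k2,k3),(k2,k4),(k3,k4); edges present: k2-k3, k2-k4
  expect_equal(rowk1$transitivity, 2 / 3)
  # patients M1 (claims k1,k2) and M3 (claims l1,k1) touch k1
  expect_equal(rowk1$n_patients, 2L)
  # both patients have claims with a PCP (k2 / l1, k1 itself too)
  expect_equal(rowk1$n_patients_with_pcp, 2L)
  # M1: PCPs k1,k2 in C1 = k1's community; M3: l1 (C2) and k1 (C1)
  expect_equal(rowk1$n_patients_with_pcp_same_community, 2L)
  # CoC: M1-2016 coc = (9+1-4)/12 = 0.5; M2 coc = 1 (k3 only)
  expect_equal(rowk1$mean_coc, 0.5)
  rowl4 <- prof[prof$provider_id == "l4", ]
  # l4 neighbors: l3 only -> degree 1, transitivity missing
  expect_equal(rowl4$degree, 1L)
  expect_true(is.na(rowl4$transitivity))
  expect_equal(rowl4$n_patients, 0L)
  # alter mean CoC of k2: neighbors k1 (0.5), k3 (1), k4 (NA -> has M2? )
  rowk2 <- prof[prof$provider_id == "k2", ]
  expect_equal(rowk2$mean_coc, 0.5)     # M1 only
})

test_that("sub-community summaries aggregate correctly", {
  profiles <- tibble::tibble(
    provider_id = sprintf("p%d", 1:5),
    specialty_group = c("pcp", "pcp", "psychiatrist", "bh_specialist",
                        "psychologist"),
    community = "C1",
    subcommunity = c(rep("C1.S1", 3), rep("C1.S2", 2)),
    degree = c(2L, 4L, 6L, 3L, 5L),
    degree_to_pcp = c(1L, 2L, 0L, 2L, 2L),
    degree_to_pcp_same_subcommunity = c(1L, 1L, 0L, 1L, 2L),
    degree_to_pcp_same_community = c(1L, 2L, 0L, 2L, 2L),
    transitivity = c(0.5, 0.25, NA, 1, 0.5),
    n_patients = c(10L, 20L, 30L, 5L, 5L),
    mean_coc = c(0.2, 0.4, NA, 0.5, 0.3))
  got <- subcommunity_summary(profiles)
  s1 <- got[got$subcommunity == "C1.S1", ]
  expect_equal(s1$size, 3L)
  expect_equal(s1$mean_connections, mean(c(2, 4, 6)))
  expect_equal(s1$mean_pcp_connections, mean(c(1, 2, 0)))
  # within-sub share over providers with >0 pcp connections: 1/1 and 1/2
  expect_equal(s1$pct_pcp_within_subcommunity, 100 * mean(c(1, 0.5)))
  expect_equal(s1$mean_transitivity, mean(c(0.5, 0.25)))
  expect_equal(s1$mean_coc, mean(c(0.2, 0.4)))
  expect_equal(s1$prop_pcp, 2 / 3)
  # empty input -> empty table
  expect_equal(nrow(subcommunity_summary(profiles[0, ])), 0)
  # network-level five-number summary
  ns <- network_summary(profiles)
  deg <- ns[ns$variable == "degree", ]
  expect_equal(c(deg$minimum, deg$median, deg$mean, deg$maximum),
               c(2, 4, 4, 6))
})
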