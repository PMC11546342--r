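small_annotated <- function(values, types, sample_id = "s1") {
  n <- ncol(values)
  em <- expression_matrix(values, rownames(values),
                          colnames(values), layer = "normalized")
  ann <- data.frame(cell_id = colnames(values), cell_type = types,
                    sample_id = sample_id, stringsAsFactors = FALSE)
  list(em = em, ann = ann)
}

test_that("type means are plain arithmetic means including zeros", {
  v <- matrix(c(2, 0, 4, 0, 1, 3), 2, 3,
              dimnames = list(c("L", "R"), c("c1", "c2", "c3")))
  f <- small_annotated(v, c("A", "A", "B"))
  me <- mean_expression_by_type(f$em, f$ann)
  col_a <- which(me$groups$cell_type == "A")
  expect_equal(unname(me$means["L", col_a]), 3)  # (2 + 4) / 2
  expect_equal(unname(me$means["R", col_a]), 0)
  expect_equal(me$groups$n_cells[me$groups$cell_type == "A"], 2L)

  # permutation invariance
  perm <- sample(ncol(v))
  f2 <- small_annotated(v[, perm], c("A", "A", "B")[perm])
  me2 <- mean_expression_by_type(f2$em, f2$ann)
  expect_equal(me2$means[, order(me2$groups$cell_type)],
               me$means[, order(me$groups$cell_type)])

  # counts layer refused unless explicit
  emc <- expression_matrix(v, layer = "counts")
  expect_error(mean_expression_by_type(emc, f$ann), "counts layer")
  expect_silent(mean_expression_by_type(emc, f$ann, allow_counts = TRUE))
})

test_that("interaction scores are exact products of means", {
  v <- matrix(c(3, 1, 3, 1, 0, 2, 0, 2), 2, 4,
              dimnames = list(c("L1", "R1"), paste0("c", 1:4)))
  f <- small_annotated(v, c("A", "A", "B", "B"))
  me <- mean_expression_by_type(f$em, f$ann)
  pairs <- data.frame(ligand = "L1", receptor = "R1")
  rec <- score_interactions(me, pairs, senders = "A", receivers = "B")
  expect_equal(rec$score, 3 * 2)  # mean ligand in A = 3, mean receptor in B = 2

  # receiver expressing zero receptor annihilates the score
  rec2 <- score_interactions(me, data.frame(ligand = "R1", receptor = "L1"),
                             senders = "B", receivers = "B")
  expect_equal(rec2$score, 2 * 0)

  # absent ligand: missing, not zero
  expect_message(
    rec3 <- score_interactions(me, data.frame(ligand = "nope",
                                              receptor = "R1"),
                               senders = "A", receivers = "B"),
    "missing")
  expect_true(is.na(rec3$score) && rec3$missing)
})

test_that("score equals brute-force product of means on random instances", {
  set.seed(83)
  for (i in 1:100) {
    n_genes <- sample(4:10, 1)
    n_cells <- sample(8:20, 1)
    genes <- sprintf("g%02d", seq_len(n_genes))
    v <- matrix(abs(rnorm(n_genes * n_cells, 2)), n_genes,
                dimnames = list(genes, sprintf("c%02d", seq_len(n_cells))))
    types <- sample(c("A", "B", "C"), n_cells, replace = TRUE,
                    prob = c(0.4, 0.4, 0.2))
    if (length(unique(types)) < 2) next
    f <- small_annotated(v, types)
    me <- mean_expression_by_type(f$em, f$ann)
    lg <- sample(genes, 1); rg <- sample(genes, 1)
    st <- sample(unique(types), 1); rt <- sample(unique(types), 1)
    rec <- score_interactions(me, data.frame(ligand = lg, receptor = rg),
                              senders = st, receivers = rt)
    brute <- mean(v[lg, types == st]) * mean(v[rg, types == rt])
    expect_equal(rec$score, brute, tolerance = 1e-12)
  }
})

test_that("scaling the ligand scales every score involving it linearly", {
  set.seed(89)
  v <- matrix(abs(rnorm(40, 2)), 4, 10,
              dimnames = list(c("L", "R", "x", "y"), paste0("c", 1:10)))
  types <- rep(c("A", "B"), each = 5)
  f <- small_annotated(v, types)
  me1 <- mean_expression_by_type(f$em, f$ann)
  pairs <- data.frame(ligand = "L", receptor = "R")
  s1 <- score_interactions(me1, pairs, "A", "B")$score
  v2 <- v; v2["L", ] <- v2["L", ] * 3.7
  f2 <- small_annotated(v2, types)
  s2 <- score_interactions(mean_expression_by_type(f2$em, f2$ann),
                           pairs, "A", "B")$score
  expect_equal(s2, 3.7 * s1, tolerance = 1e-12)
})

test_that("cross-sample averaging respects missing-data contracts", {
  recs <- data.frame(ligand = "L", receptor = "R", sender = "A",
                     receiver = "B",
                     sample_id = c("s1", "s2", "s3"),
                     score = c(2, 4, 6), missing = FALSE)
  expect_equal(average_scores_across_samples(recs)$mean_score, 4)
  one <- recs[1, ]
  expect_equal(average_scores_across_samples(one)$mean_score, 2)
  holey <- recs; holey$score[2] <- NA
  avg <- average_scores_across_samples(holey)
  expect_equal(avg$mean_score, 4)
  expect_equal(avg$n_samples, 2L)
  allna <- recs; allna$score <- NA
  expect_warning(out <- average_scores_across_samples(allna), "every sample")
  expect_equal(nrow(out), 0L)
})

test_that("intersection-union significance takes the worse component", {
  set.seed(97)
  v <- matrix(abs(rnorm(120, 1)), 3, 40,
              dimnames = list(c("L", "R", "z"), sprintf("c%02d", 1:40)))
  types <- rep(c("A", "B", "C", "D"), each = 10)
  v["L", types == "A"] <- v["L", types == "A"] + 4   # ligand enriched in A
  # receptor NOT enriched anywhere
  f <- small_annotated(v, types)
  sig <- interaction_significance(f$em, f$ann, "L", "R", "A", "B")
  expect_equal(sig$p, max(sig$p_ligand, sig$p_receptor))
  expect_lt(sig$p_ligand, 0.01)
  expect_gt(sig$p, 0.05)  # the weak receptor side dominates

  v["R", types == "B"] <- v["R", types == "B"] + 4
  f2 <- small_annotated(v, types)
  sig2 <- interaction_significance(f2$em, f2$ann, "L", "R", "A", "B")
  expect_lt(sig2$p, 0.01)

  # direction: expression strictly below the rest pushes p toward 1
  v3 <- v; v3["L", types == "A"] <- 0
  f3 <- small_annotated(v3, types)
  sig3 <- interaction_significance(f3$em, f3$ann, "L", "L", "A", "A")
  expect_gt(sig3$p, 0.95)

  # all-tied data gives p = 1
  v4 <- matrix(2, 2, 8, dimnames = list(c("L", "R"), paste0("c", 1:8)))
  f4 <- small_annotated(v4, rep(c("A", "B"), each = 4))
  expect_equal(interaction_significance(f4$em, f4$ann, "L", "R",
                                        "A", "B")$p, 1)
})

test_that("the vectorized enrichment matrix equals the per-record test", {
  set.seed(101)
  v <- matrix(rpois(200, 2) * rbinom(200, 1, 0.7), 5, 40,
              dimnames = list(sprintf("g%d", 1:5), sprintf("c%02d", 1:40)))
  types <- sample(c("A", "B", "C"), 40, replace = TRUE)
  em <- expression_matrix(v, layer = "normalized")
  ann <- data.frame(cell_id = colnames(v), cell_type = types,
                    sample_id = "s1")
  P <- lrcomms:::wilcoxon_enrichment_matrix(em, types)
  for (g in rownames(v)) {
    for (t_ in unique(types)) {
      sig <- interaction_significance(em, ann, g, g, t_, t_)
      expect_equal(P[g, t_], sig$p_ligand, tolerance = 1e-12)
    }
  }
})

test_that("phenotype association recovers monotone relations exactly", {
  recs <- data.frame(ligand = "L", receptor = "R", sender = "A",
                     receiver = "B", sample_id = paste0("s", 1:4),
                     score = c(1, 2, 3, 4), missing = FALSE)
  ph <- data.frame(sample_id = paste0("s", 1:4),
                   phenotype = c(10, 20, 30, 40))
  expect_equal(phenotype_association(recs, ph)$rho_score, 1)
  ph$phenotype <- rev(ph$phenotype)
  expect_equal(phenotype_association(recs, ph)$rho_score, -1)
  # constant score series is flagged degenerate
  recs$score <- 2
  out <- phenotype_association(recs, ph)
  expect_true(out$degenerate)
  expect_true(is.na(out$rho_score))
})

test_that("receptor/ligand decomposition classifies planted geometries", {
  samples <- paste0("s", 1:8)
  ph <- data.frame(sample_id = samples, phenotype = 1:8)
  build_me <- function(lig_series, rec_series) {
    # one sender-type cell and one receiver-type cell per sample
    cells <- c(paste0(samples, "_snd"), paste0(samples, "_rcv"))
    v <- matrix(0.01, 2, 16, dimnames = list(c("L", "R"), cells))
    v["L", 1:8] <- lig_series
    v["R", 9:16] <- rec_series
    em <- expression_matrix(v, layer = "normalized")
    ann <- data.frame(cell_id = cells,
                      cell_type = rep(c("snd", "rcv"), each = 8),
                      sample_id = rep(samples, 2))
    mean_expression_by_type(em, ann)
  }
  assoc0 <- data.frame(ligand = "L", receptor = "R", sender = "snd",
                       receiver = "rcv", rho_score = 1, p_assoc = 0.001,
                       q_assoc = 0.001, n_used = 8, degenerate = FALSE)

  # receptor tracks phenotype, ligand flat noise
  me <- build_me(c(2.0, 2.1, 1.9, 2.05, 1.95, 2.02, 1.98, 2.0), 1:8)
  out <- decompose_association(assoc0, me, ph)
  expect_equal(out$quadrant_class, "receptor_driven")

  # both track the phenotype
  me2 <- build_me(seq(1, 4, length.out = 8), 1:8)
  expect_equal(decompose_association(assoc0, me2, ph)$quadrant_class,
               "both_strong")

  # only the product tracks: anticorrelated components inside the band
  lig <- c(2.702, 0.716, 1.221, 1.118, 2.905, 1.844, 3.194, 2.242)
  rec <- (1:8) / lig
  # product is increasing in the phenotype while each factor stays weak
  expect_true(all(diff(lig * rec) > 0))
  me3 <- build_me(lig, rec)
  out3 <- decompose_association(assoc0, me3, ph)
  expect_lte(abs(out3$rho_receptor), 0.5)
  expect_lte(abs(out3$rho_ligand), 0.5)
  expect_equal(out3$quadrant_class, "interaction_only")
})

test_that("the planted channel wins end to end at study conditions", {
  fx <- planted_channel_fixture(seed = 11)
  res <- suppressMessages(
    score_and_test_interactions(fx$normalized, fx$sim$annotation, fx$pairs))
  summ <- res$summary
  top <- summ[which.max(summ$mean_score), ]
  expect_equal(top$ligand, "gene0005")
  expect_equal(top$receptor, "gene0006")
  expect_equal(top$sender, "type01")
  expect_equal(top$receiver, "type02")
  expect_lt(top$min_q, 0.05)

  ph <- simulate_phenotype_series(fx$sim$truth, slope = 1, noise_sd = 0.02,
                                  seed = 12)
  assoc <- phenotype_association(res$records, ph)
  planted <- assoc$ligand == "gene0005" & assoc$sender == "type01" &
    assoc$receiver == "type02"
  # measured at seed 11: rho = 0.909
  expect_gte(abs(assoc$rho_score[planted]), 0.8)
  expect_gt(assoc$rho_score[planted] * 1, 0)  # sign of the planted slope
  expect_lt(assoc$q_assoc[planted], 0.05)
})
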