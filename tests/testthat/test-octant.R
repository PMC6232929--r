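test_that("the octant table is a complete labeled sign cube", {
  tab <- octant_model()$octants
  expect_equal(nrow(tab), 8L)
  expect_equal(anyDuplicated(tab[, c("dorsal", "anterior", "lateral")]), 0L)
  expect_true(all(tab$dorsal[tab$octant <= 4] == 1))
  expect_true(all(tab$dorsal[tab$octant >= 5] == -1))
  expect_identical(tab$name,
                   c("ADL", "PDL", "PDM", "ADM", "AVM", "PVM", "PVL", "AVL"))
  expect_error(octant_model(dv = list(positive = character(0),
                                      negative = "Lfng")),
               class = "otoctant_config_error")
})

test_that("axis scores contrast pole panels on the scaled scale", {
  genes <- octant_model_genes(octant_model())
  v <- matrix(0, 2, length(genes), dimnames = list(c("c1", "c2"), genes))
  v["c1", c("Oc90", "Bmp4", "Wnt2b")] <- 1   # saturated dorsal markers
  v["c2", ] <- 0.4                           # all panels equal
  e <- toy_expr(v)
  s <- compute_axis_scores(e, model = octant_model())
  expect_equal(s["c1", "dv"], 1)
  expect_equal(unname(s["c2", ]), c(0, 0, 0))
  expect_true(all(s >= -1 & s <= 1))
  e_bad <- toy_expr(v[, -1, drop = FALSE])
  expect_error(compute_axis_scores(e_bad, model = octant_model()),
               class = "otoctant_config_error")
})

test_that("octant assignment looks up sign triples with positive tie-breaks", {
  m <- octant_model()
  scores <- rbind(c1 = c(0.5, 0.5, 0.5),    # +++ -> ADL
                  c2 = c(-0.5, 0.5, -0.5),  # -+- -> AVM
                  c3 = c(0.5, 0, 0.2),      # zero AP tie-broken anterior
                  c4 = c(0, 0, 0))          # degenerate: center
  colnames(scores) <- c("dv", "ap", "ml")
  a <- assign_octants(scores, m)
  expect_identical(a$octant_name[1:3], c("ADL", "AVM", "ADL"))
  expect_true(a$center_flag[4])
  expect_true(is.na(a$octant[4]))
  expect_equal(attr(a, "n_zero_ties"), 4L)
  # sphere coordinates are unit length off-center
  expect_equal(sqrt(a$sphere_dv[1]^2 + a$sphere_ap[1]^2 + a$sphere_ml[1]^2), 1)

  # flipping an axis's pole panels flips that sign for every cell
  flipped <- octant_model(dv = list(positive = "Lfng",
                                    negative = c("Oc90", "Bmp4", "Wnt2b")))
  st <- generate_study(generator_spec(rng_seed = 13, cells_per_embryo = 20))
  pre <- preprocess(st$ct)
  epi <- st$truth$cell_id[st$truth$identity == "otic_epithelial" &
                            st$truth$cell_id %in% rownames(pre$expr$values)]
  s1 <- compute_axis_scores(pre$expr, epi, octant_model())
  s2 <- compute_axis_scores(pre$expr, epi, flipped)
  expect_equal(s2[, "dv"], -s1[, "dv"])
  expect_equal(s2[, "ap"], s1[, "ap"])
})

test_that("noise-free reconstruction reproduces ground-truth octants exactly", {
  st <- generate_study(noise_free_spec(seed = 2))
  res <- run_pipeline(st$ct, seed = 2)
  tr <- st$truth[match(res$assignment$cell_id, st$truth$cell_id), ]
  ok <- tr$identity == "otic_epithelial"   # guard against any mislabeling
  expect_gte(mean(ok), 0.99)
  expect_false(any(res$assignment$center_flag[ok]))
  expect_identical(res$assignment$octant[ok], tr$octant[ok])
  # octant counts partition the placed epithelial cells
  expect_equal(sum(table(res$assignment$octant)),
               sum(!res$assignment$center_flag))
})

test_that("noisy reconstruction still recovers most octants", {
  st <- generate_study(generator_spec(rng_seed = 14))
  res <- run_pipeline(st$ct, seed = 14)
  tr <- st$truth[match(res$assignment$cell_id, st$truth$cell_id), ]
  keep <- tr$identity == "otic_epithelial" & !res$assignment$center_flag
  expect_gte(mean(res$assignment$octant[keep] == tr$octant[keep]), 0.85)
})

test_that("octant summaries report percent expressing and level quartiles", {
  genes <- octant_model_genes(octant_model())
  v <- matrix(0, 4, length(genes) + 1,
              dimnames = list(paste0("c", 1:4), c(genes, "gX")))
  v[, "Oc90"] <- 0.6; v[, "Bmp4"] <- 0.7; v[, "Wnt2b"] <- 0.8
  v["c1", "gX"] <- 0.5                       # 1 of 4 cells expressing gX
  e <- toy_expr(v)
  scores <- compute_axis_scores(e, model = octant_model())
  a <- assign_octants(scores)
  expect_true(all(a$octant_name == "ADL"))   # dorsal high, others tied +
  sm <- octant_summary(e, a, genes = "gX")
  row <- sm[sm$octant == 1 & sm$genotype == "wildtype", ]
  expect_equal(row$n, 4L)
  expect_equal(row$pct_expressing, 25)
  expect_equal(unlist(row[, c("min", "q1", "median", "q3", "max")],
                      use.names = FALSE), rep(0.5, 5))
  sm2 <- octant_summary(e, a, genes = "Oc90")
  expect_equal(unlist(sm2[sm2$octant == 1 & sm2$genotype == "wildtype",
                          c("min", "median", "max")], use.names = FALSE),
               c(0.6, 0.6, 0.6))
  # empty octants report no level summary
  expect_true(all(is.na(sm$median[sm$n == 0])))

  # generator gradient: dorsal markers detected more often dorsally
  st <- generate_study(generator_spec(rng_seed = 15))
  res <- run_pipeline(st$ct, seed = 15)
  s <- res$summary[res$summary$gene %in% c("Oc90", "Bmp4", "Wnt2b") &
                     res$summary$n > 0, ]
  dorsal <- s$pct_expressing[s$octant <= 4]
  ventral <- s$pct_expressing[s$octant >= 5]
  expect_gt(mean(dorsal), mean(ventral))
})

test_that("differential tests match closed forms and respect group minima", {
  # identical groups: level test is exactly null
  v <- matrix(0.5, 12, length(octant_model_genes(octant_model())) + 1)
  genes <- c(octant_model_genes(octant_model()), "gX")
  dimnames(v) <- list(paste0("c", 1:12), genes)
  v[, c("Oc90", "Bmp4", "Wnt2b")] <- 0.9
  meta <- toy_meta(rownames(v),
                   genotype = rep(c("wildtype", "mutant"), each = 6))
  e <- toy_expr(v, meta = meta)
  a <- assign_octants(compute_axis_scores(e, model = octant_model()))
  d <- differential_octant_expression(e, a, genes = "gX")
  row <- d[d$octant == 1, ]
  expect_equal(row$p_level, 1)
  expect_equal(row$t_level, 0)
  expect_equal(row$delta_pct, 0)

  # all-or-none detection: Fisher p equals the hypergeometric closed form
  v2 <- v
  v2[meta$genotype == "mutant", "gX"] <- 0   # 6/6 vs 0/6 expressing
  e2 <- toy_expr(v2, meta = meta)
  d2 <- differential_octant_expression(e2, a, genes = "gX")
  row2 <- d2[d2$octant == 1, ]
  expect_equal(row2$p_fraction, fisher_oracle(6, 0, 0, 6), tolerance = 1e-12)
  expect_equal(fisher_oracle(10, 0, 0, 10), 2 / choose(20, 10))
  expect_true(is.na(row2$p_level))           # < min_cells expressing mutants
  expect_true(row2$significant)

  # Welch and Fisher agree with independent oracles on random small tables
  set.seed(7)
  for (i in 1:40) {
    n1 <- sample(2:10, 1); n2 <- sample(2:10, 1)
    x <- runif(n1); y <- runif(n2)
    expect_lt(abs(welch_test(x, y)$p - welch_oracle(x, y)$p), 1e-9)
    a1 <- rbinom(1, n1, 0.5); c1 <- rbinom(1, n2, 0.5)
    expect_lt(abs(stats::fisher.test(matrix(c(a1, n1 - a1, c1, n2 - c1),
                                            2))$p.value -
                    fisher_oracle(a1, n1 - a1, c1, n2 - c1)), 1e-9)
  }
})

test_that("the Notch panel report detects an injected ventral upshift", {
  st <- generate_study(generator_spec(rng_seed = 30, notch_upshift = 2))
  res <- run_pipeline(st$ct, seed = 30)
  rep <- res$notch
  expect_length(rep$missing, 0)
  vent <- rep$table[rep$table$compartment == "ventral" &
                      !is.na(rep$table$delta_level), ]
  expect_gt(mean(vent$delta_level > 0), 0.8)
  agg <- rep$aggregate
  expect_gt(agg$mean_delta_level[agg$compartment == "ventral"], 0)

  # null generator: no consistent panel direction in either compartment
  stn <- generate_null_study(generator_spec(rng_seed = 31))
  resn <- run_pipeline(stn$ct, seed = 31)
  aggn <- resn$notch$aggregate
  expect_lt(max(abs(aggn$mean_delta_level)), 0.06)

  # empty panel intersection warns and returns empty
  expect_warning(empty <- notch_panel_report(res$differential,
                                             panel = "NotAGene"))
  expect_equal(nrow(empty$table), 0L)
  expect_identical(empty$missing, "NotAGene")
})
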