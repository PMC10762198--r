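# Jaccard table, triple-condition subnetwork derivation, robustness.

test_that("Jaccard table matches hand counts and records empty unions as NA", {
  # A present in samples 1,2,3; B in 3,4; group of 5 -> J = 1/4
  counts <- toy_table(rbind(A = c(1, 2, 3, 0, 0),
                            B = c(0, 0, 9, 1, 0),
                            C = c(1, 1, 1, 1, 1),
                            D = c(0, 0, 0, 0, 0)))
  md <- data.frame(sample = paste0("s", 1:5), region = "R1", layer = "SRF")
  edges <- data.frame(a = c("A", "C", "D"), b = c("B", "A", "D2"))
  counts$counts <- rbind(counts$counts, D2 = rep(0L, 5))
  counts$domain <- c(counts$domain, D2 = "Bacteria")
  jt <- jaccard_table(counts, md, edges)
  expect_equal(jt$jaccard[jt$a == "A" & jt$b == "B"], 0.25)
  expect_equal(jt$jaccard[jt$a == "C"], 0.6)          # C everywhere, A in 3/5
  expect_true(is.na(jt$jaccard[jt$a == "D"]))         # empty union
  expect_error(jaccard_table(counts, md, data.frame(a = "A", b = "ZZ")),
               "absent")
})

test_that("derivation honours the three conditions with a strict threshold", {
  counts <- toy_table(rbind(A = c(5, 5, 5, 5, 0),
                            B = c(1, 1, 1, 0, 2),
                            C = c(0, 0, 1, 1, 1),
                            D = c(3, 0, 0, 7, 0)))
  md <- data.frame(sample = paste0("s", 1:5), region = "R1", layer = "SRF")
  net <- static_network(data.frame(a = c("A", "A", "B"),
                                   b = c("B", "C", "D"),
                                   score = c(0.8, 0.5, 0.4)))
  jt <- jaccard_table(counts, md, net$edges)
  # J(A,B) = 3/5, J(A,C) = 2/5, J(B,D) = 1/5 = 0.20 exactly
  # (B in s1,s2,s3,s5; D in s1,s4: both = {s1}, either = 5 samples)
  sub1 <- derive_subnetwork("s1", counts, md, net, jt, threshold = 0.20)
  k <- pelagicnets:::edge_key(sub1$edges$a, sub1$edges$b)
  expect_true("A|B" %in% k)        # both present, J 0.6
  expect_false("A|C" %in% k)       # C absent in s1 (condition ii)
  expect_false("B|D" %in% k)       # J exactly at threshold -> excluded
  # raising J threshold to where A|B fails
  sub2 <- derive_subnetwork("s1", counts, md, net, jt, threshold = 0.6)
  expect_equal(nrow(sub2$edges), 0)
  expect_equal(length(sub2$nodes), 0)  # no isolated nodes
  expect_error(derive_subnetwork("nope", counts, md, net, jt), "not found")
})

test_that("derive_all equals the brute-force oracle on a synthetic fixture", {
  d <- tiny_dataset()
  counts <- pelagicnets:::combine_asv_tables(d$prok_counts, d$euk_counts)
  net <- truth_static_network(d, n_background_edges = 10, seed = 13)
  subs <- derive_all(counts, d$metadata, net, 0.2)
  expect_length(subs$subnetworks, nrow(d$metadata))
  set.seed(14)
  for (s in sample(d$metadata$sample, 6)) {
    got <- sort(pelagicnets:::edge_key(subs$subnetworks[[s]]$edges$a,
                                       subs$subnetworks[[s]]$edges$b))
    expect_identical(got,
                     oracle_subnetwork_edges(s, counts, d$metadata, net, 0.2))
  }
  # every subnetwork: edges subset of static, min degree >= 1, endpoints present
  static_keys <- pelagicnets:::edge_key(net$edges$a, net$edges$b)
  for (s in subs$subnetworks) {
    expect_true(all(pelagicnets:::edge_key(s$edges$a, s$edges$b) %in%
                      static_keys))
    expect_setequal(s$nodes, unique(c(s$edges$a, s$edges$b)))
    expect_true(all(counts$counts[s$nodes, s$sample] > 0))
  }
})

test_that("subnetworks are invariant to sample and ASV ordering", {
  d <- tiny_dataset()
  counts <- pelagicnets:::combine_asv_tables(d$prok_counts, d$euk_counts)
  net <- truth_static_network(d, n_background_edges = 5, seed = 15)
  base <- derive_all(counts, d$metadata, net, 0.2)
  set.seed(16)
  md2 <- d$metadata[sample(nrow(d$metadata)), ]
  counts2 <- counts
  perm <- sample(nrow(counts$counts))
  counts2$counts <- counts$counts[perm, ]
  counts2$domain <- counts$domain[perm]
  counts2$taxonomy <- counts$taxonomy[perm]
  shuf <- derive_all(counts2, md2, net, 0.2)
  for (s in d$metadata$sample) {
    expect_setequal(pelagicnets:::edge_key(base$subnetworks[[s]]$edges$a,
                                           base$subnetworks[[s]]$edges$b),
                    pelagicnets:::edge_key(shuf$subnetworks[[s]]$edges$a,
                                           shuf$subnetworks[[s]]$edges$b))
  }
})

test_that("raising the threshold only shrinks subnetworks; 1.0 empties them", {
  d <- tiny_dataset()
  counts <- pelagicnets:::combine_asv_tables(d$prok_counts, d$euk_counts)
  net <- truth_static_network(d, n_background_edges = 5, seed = 17)
  lo <- derive_all(counts, d$metadata, net, 0.2)
  hi <- derive_all(counts, d$metadata, net, 0.5)
  top <- derive_all(counts, d$metadata, net, 1.0)
  for (s in d$metadata$sample) {
    expect_true(all(pelagicnets:::edge_key(hi$subnetworks[[s]]$edges$a,
                                           hi$subnetworks[[s]]$edges$b) %in%
                      pelagicnets:::edge_key(lo$subnetworks[[s]]$edges$a,
                                             lo$subnetworks[[s]]$edges$b)))
    expect_equal(nrow(top$subnetworks[[s]]$edges), 0)
  }
})

test_that("robustness subsampling rounds sizes up and is seed-stable", {
  d <- tiny_dataset()
  counts <- pelagicnets:::combine_asv_tables(d$prok_counts, d$euk_counts)
  net <- truth_static_network(d, n_background_edges = 5, seed = 18)
  md7 <- d$metadata[d$metadata$region == "MS", ][1:7, ]
  rb <- subsample_robustness(counts, md7, net, fractions = c(0.1, 0.9),
                             reps = 20, seed = 4)
  expect_equal(rb$subset_size[rb$fraction == 0.1], 1)  # ceil(0.7)
  r1 <- subsample_robustness(counts, md7, net, fractions = 0.5, reps = 10,
                             seed = 9)
  r2 <- subsample_robustness(counts, md7, net, fractions = 0.5, reps = 10,
                             seed = 9)
  expect_identical(r1, r2)
  # a fraction rounding to the full group reproduces it exactly
  rfull <- subsample_robustness(counts, md7, net, fractions = 0.99, reps = 3,
                                seed = 1)
  expect_equal(rfull$mean_kept_ratio, 1)
  expect_equal(rfull$mean_identity_kept, 1)
  # single-sample groups are skipped with a notice
  md1 <- d$metadata[1, ]
  expect_message(out <- subsample_robustness(counts, md1, net,
                                             fractions = 0.5, reps = 2,
                                             seed = 1),
                 "only one sample")
  expect_null(out)
})

test_that("identity-kept fraction rises with the subsample fraction", {
  d <- tiny_dataset()
  counts <- pelagicnets:::combine_asv_tables(d$prok_counts, d$euk_counts)
  net <- truth_static_network(d, n_background_edges = 8, seed = 19)
  md <- d$metadata[d$metadata$region == "NAO" & d$metadata$layer == "SRF", ]
  rb <- subsample_robustness(counts, md, net,
                             fractions = c(0.2, 0.5, 0.8), reps = 200,
                             seed = 10)
  expect_true(all(diff(rb$mean_identity_kept) >= 0))
})
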