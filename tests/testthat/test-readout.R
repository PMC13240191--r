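payload <- random_bytes(150, 12)
enc <- encode_archive(payload, g = 4)
manifest <- enc$manifest

test_that("demux partitions every read and assigns all error-free reads", {
  reads <- sim_pool_reads(enc$strands, channel_params(0, 0, 0, depth_mean = 6),
                          seed = 1)
  dm <- demux(reads, manifest)
  expect_identical(nrow(dm$assignments) + length(dm$unassigned), nrow(reads))
  expect_identical(length(dm$unassigned), 0L)
  # assignments agree with the simulator's ground truth
  expect_identical(dm$assignments$index,
                   as.integer(reads$index[dm$assignments$read]))
})

test_that("primerless random reads are unassigned; one substitution in a primer is tolerated", {
  rnd <- with_seed(2, data.frame(
    sequence = vapply(1:20, function(i)
      paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = ""),
      character(1))))
  dm <- demux(rnd, manifest)
  expect_identical(nrow(dm$assignments), 0L)
  expect_identical(length(dm$unassigned), 20L)
  # mutate one base inside the 5' primer: score 19*1 - 1 = 18 >= 0.8 * 20
  s <- enc$strands$sequence[1]
  ch <- strsplit(s, "")[[1]]
  ch[10] <- setdiff(c("A", "C", "G", "T"), ch[10])[1]
  dm <- demux(data.frame(sequence = paste(ch, collapse = "")), manifest)
  expect_identical(nrow(dm$assignments), 1L)
  expect_identical(dm$assignments$index, 0L)
})

test_that("consensus takes the per-position plurality with deterministic ties", {
  tmpl <- enc$strands$sequence[1]
  expect_identical(consensus(rep(tmpl, 3), 150L), tmpl)
  # depth 5 with one read carrying one substitution: plurality 4 vs 1
  ch <- strsplit(tmpl, "")[[1]]
  ch[30] <- setdiff(c("A", "C", "G", "T"), ch[30])[1]
  expect_identical(consensus(c(rep(tmpl, 4), paste(ch, collapse = "")), 150L),
                   tmpl)
  expect_identical(consensus(character(0), 150L), NA_character_)
  # length-nonconforming reads are excluded from the positional vote
  expect_identical(consensus(c(tmpl, substr(tmpl, 1, 100)), 150L), tmpl)
  expect_identical(consensus(substr(tmpl, 1, 100), 150L), NA_character_)
  # 1-1 tie resolved in fixed base order A < C < G < T
  expect_identical(consensus(c("AA", "CA"), 2L), "AA")
  expect_identical(consensus(c("GT", "TT"), 2L), "GT")
})

test_that("perfect-match accounting: depth, exact equality, ratio, aggregates", {
  reads <- sim_pool_reads(enc$strands, channel_params(0, 0, 0, depth_mean = 10),
                          seed = 3)
  dm <- demux(reads, manifest)
  pm <- perfect_match_stats(dm, reads, enc$strands)
  expect_true(all(pm$ratio == 1))
  expect_identical(sum(pm$depth), nrow(reads))
  expect_equal(attr(pm, "perfect_pct"), 100)
  # mutate exactly one of two reads at one index
  two <- reads[reads$index == 0, ][1:2, ]
  ch <- strsplit(two$sequence[2], "")[[1]]
  ch[75] <- setdiff(c("A", "C", "G", "T"), ch[75])[1]
  two$sequence[2] <- paste(ch, collapse = "")
  dm2 <- demux(two, manifest)
  pm2 <- perfect_match_stats(dm2, two, enc$strands)
  expect_equal(pm2$ratio[pm2$index == 0], 0.5)
  # under substitution rate p the perfect fraction concentrates near (1-p)^L
  p <- 0.01
  noisy <- sim_pool_reads(enc$strands, channel_params(p, 0, 0, depth_mean = 40),
                          seed = 5)
  dmn <- demux(noisy, manifest)
  pmn <- perfect_match_stats(dmn, noisy, enc$strands)
  frac <- sum(pmn$perfect) / sum(pmn$depth)
  expected <- (1 - p)^150
  sigma <- sqrt(expected * (1 - expected) / sum(pmn$depth))
  expect_lt(abs(frac - expected), 3 * sigma)
})

test_that("zero-noise pipeline is the identity on payload bytes", {
  reads <- sim_pool_reads(enc$strands, channel_params(0, 0, 0, depth_mean = 8),
                          seed = 6)
  out <- decode_pipeline(reads, manifest)
  expect_identical(out$bytes, payload)
  expect_true(all(out$report$status == "recovered"))
})

test_that("an index with no reads at all is repaired through XOR", {
  reads <- sim_pool_reads(enc$strands, channel_params(0, 0, 0, depth_mean = 8),
                          seed = 7)
  reads <- reads[reads$index != 2, ]
  out <- decode_pipeline(reads, manifest)
  expect_identical(out$bytes, payload)
  expect_identical(out$report$status[out$report$index == 2], "xor_recovered")
})

test_that("consensus error is non-increasing in depth at fixed substitution rate", {
  tmpl <- setNames(enc$strands$sequence, enc$strands$index)
  deep <- sim_pool_reads(enc$strands,
                         channel_params(0.02, 0, 0, depth_mean = 60,
                                        depth_dispersion = 1e6), seed = 11)
  err <- vapply(c(1, 3, 10, 30), function(d) {
    rates <- vapply(enc$strands$index, function(ix) {
      cs <- consensus(reads_at_depth(deep, ix, d), 150L)
      if (is.na(cs)) return(NA_real_)
      hamming_dist(cs, tmpl[[as.character(ix)]]) / 150
    }, numeric(1))
    mean(rates, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(err) <= 0))
  expect_gt(err[1], err[4])
})

test_that("mesh decode repairs lost coordinates with the modified-IQR rule", {
  mesh <- make_fixture("mesh", seed = 5, n_vertices = 60, n_faces = 60)
  encm <- encode_archive(serialize_mesh(mesh), g = 4, content = "mesh")
  reads <- sim_pool_reads(encm$strands,
                          channel_params(0, 0, 0, depth_mean = 8), seed = 8)
  # wipe two data strands of the second group (away from the mesh header)
  grp2 <- which(encm$manifest$group_of_index == 2)[1:2] - 1L
  reads <- reads[!reads$index %in% grp2, ]
  out <- decode_pipeline(reads, encm$manifest)
  expect_identical(sum(out$report$status == "lost"), 2L)
  expect_gt(nrow(out$lost_ranges), 0L)
  expect_false(is.null(out$repaired))
  # zero-sentinel coordinates near 0 are in-range for this mesh, so repaired
  # values stay within the IQR bounds axis-wise
  for (a in 1:3) {
    adj <- out$repaired[[a]]
    expect_true(all(adj$values >= adj$lower - 1e-9 &
                      adj$values <= adj$upper + 1e-9 | !adj$outliers))
  }
})
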