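test_that("fragmentation and XOR overhead arithmetic hold", {
  enc <- encode_archive(random_bytes(25, 1), g = 4)
  # 25 bytes at 19 data bytes per strand -> 2 data strands, pad 13
  expect_identical(enc$manifest$n_data, 2L)
  expect_identical(enc$manifest$pad, 13L)
  for (nd_seed in 1:6) {
    nbytes <- with_seed(nd_seed, sample(20:900, 1))
    g <- with_seed(nd_seed + 50, sample(c(2L, 4L, 8L), 1))
    enc <- encode_archive(random_bytes(nbytes, nd_seed), g = g)
    nd <- ceiling(nbytes / 19)
    expect_identical(enc$manifest$n_data, as.integer(nd))
    expect_identical(enc$manifest$n_parity, as.integer(ceiling(nd / g)))
    expect_identical(nrow(enc$strands), as.integer(nd + ceiling(nd / g)))
    expect_true(all(nchar(enc$strands$sequence) == 150L))
  }
  expect_error(encode_archive(integer(0)), "non-empty")
})

test_that("three data strands with g = 2 yield two parity strands", {
  enc <- encode_archive(random_bytes(3 * 19, 2), g = 2)
  expect_identical(enc$manifest$n_data, 3L)
  expect_identical(enc$manifest$n_parity, 2L)
  expect_identical(nrow(enc$strands), 5L)
})

test_that("perfect consensus decodes bit-exact with zero XOR recoveries", {
  payload <- random_bytes(300, 3)
  enc <- encode_archive(payload, g = 8)
  dec <- decode_archive(enc$strands$sequence, enc$manifest)
  expect_identical(dec$payload, payload)
  expect_true(all(dec$report$status == "recovered"))
  expect_identical(nrow(dec$lost_ranges), 0L)
})

test_that("deleting one strand per group is repaired bit-exact, two losses are flagged", {
  payload <- random_bytes(8 * 19, 4)
  enc <- encode_archive(payload, g = 4)   # 8 data + 2 parity
  n_groups <- enc$manifest$n_parity
  # exhaustive single-deletion sweep over every strand
  for (drop in seq_len(nrow(enc$strands))) {
    cons <- enc$strands$sequence
    cons[drop] <- NA
    dec <- decode_archive(cons, enc$manifest)
    expect_identical(dec$payload, payload)
    expect_identical(sum(dec$report$status == "xor_recovered"), 1L)
  }
  # one deletion in every group at once: recoveries = group count
  cons <- enc$strands$sequence
  first_of_group <- vapply(seq_len(n_groups), function(g)
    which(enc$manifest$group_of_index == g)[1], integer(1))
  cons[first_of_group] <- NA
  dec <- decode_archive(cons, enc$manifest)
  expect_identical(dec$payload, payload)
  expect_identical(sum(dec$report$status == "xor_recovered"),
                   as.integer(n_groups))
  # two losses in one group: exactly that group's data region lost
  cons <- enc$strands$sequence
  cons[1:2] <- NA   # indices 0 and 1 are both in group 1 (g = 4)
  dec <- decode_archive(cons, enc$manifest)
  expect_identical(dec$report$status[1:2], c("lost", "lost"))
  expect_true(all(dec$report$status[-(1:2)] == "recovered"))
  expect_identical(dec$lost_ranges$from, c(1L, 20L))
  expect_identical(dec$payload[39:length(payload)], payload[39:length(payload)])
})

test_that("mesh serialization round trips and obeys the declared byte budget", {
  tet <- mesh_3d(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                 rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)))
  back <- deserialize_mesh(serialize_mesh(tet))
  expect_equal(back$vertices, tet$vertices)
  expect_identical(back$faces, tet$faces)
  empty <- mesh_3d(matrix(numeric(0), ncol = 3), matrix(integer(0), ncol = 3))
  expect_identical(length(serialize_mesh(empty)), 5L)
  expect_identical(nrow(deserialize_mesh(serialize_mesh(empty))$vertices), 0L)
  cube <- make_fixture("mesh")
  # header 5 + 3 * 8 vertices * 2 bytes + 3 * 12 faces * 2 bytes
  expect_identical(length(serialize_mesh(cube)), 5L + 48L + 72L)
  back <- deserialize_mesh(serialize_mesh(cube))
  expect_equal(back$vertices, cube$vertices)
  expect_identical(back$faces, cube$faces)
  big <- mesh_3d(matrix(c(300, 0, 0), ncol = 3), matrix(integer(0), ncol = 3))
  expect_error(serialize_mesh(big), "quantization")
})

test_that("pixel profile arithmetic and round trips", {
  layout <- pixel_layout()
  expect_identical(layout$payload_len, 90L - 20L - 20L - 2L)  # 48 nt
  img <- make_fixture("image", seed = 3)
  st <- encode_pixels(img)
  expect_identical(nrow(st), 8L)
  expect_true(all(nchar(st$sequence) == 90L))
  dec <- decode_pixels(st$sequence, attr(st, "pixel_spec"))
  expect_identical(dec$grid, img$grid)
  flat <- pixel_image(matrix(2L, 16, 16), bits = 2L)
  st2 <- encode_pixels(flat)
  expect_identical(decode_pixels(st2$sequence, attr(st2, "pixel_spec"))$grid,
                   flat$grid)
  huge <- pixel_image(matrix(0L, 16, 64), bits = 2L)
  expect_error(encode_pixels(huge), "capacity")
})

test_that("modified-IQR repair follows the declared quantile convention", {
  # hand-computed under linear interpolation: Q1 = 2, Q3 = 4, IQR = 2,
  # upper = 4 + 0.55 * 2 = 5.1
  r <- adjust_outliers_iqr(c(1, 2, 3, 4, 100))
  expect_equal(r$upper, 5.1)
  expect_equal(r$lower, 0.9)
  expect_identical(which(r$outliers), 5L)
  expect_equal(r$values, c(1, 2, 3, 4, 5.1))
  # constant list: IQR = 0, bounds equal, nothing changes
  r <- adjust_outliers_iqr(rep(2, 6))
  expect_false(any(r$outliers))
  expect_equal(r$values, rep(2, 6))
  # clean symmetric data untouched
  r <- adjust_outliers_iqr(1:8 / 2)
  expect_false(any(r$outliers))
  # only flagged values are candidates
  r <- adjust_outliers_iqr(c(1, 2, 3, 4, 100), flags = c(rep(TRUE, 4), FALSE))
  expect_false(any(r$outliers))
  expect_error(adjust_outliers_iqr(c(1, 2, 3)), "at least 4")
})

test_that("IQR bounds are monotone in k and vanish as k grows", {
  v <- c(1, 2, 3, 4, 50, -30)
  widths <- vapply(c(0.55, 1, 2, 5, 100), function(k) {
    r <- adjust_outliers_iqr(v, policy = outlier_policy(k = k))
    r$upper - r$lower
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
  r <- adjust_outliers_iqr(v, policy = outlier_policy(k = 1e6))
  expect_false(any(r$outliers))
})

test_that("mesh -> archive -> decode is identity for random toy meshes", {
  for (seed in 1:3) {
    mesh <- make_fixture("mesh", seed = seed, n_vertices = 40, n_faces = 50)
    enc <- encode_archive(serialize_mesh(mesh), content = "mesh")
    dec <- decode_archive(enc$strands$sequence, enc$manifest)
    back <- deserialize_mesh(dec$payload)
    expect_equal(back$vertices, mesh$vertices)
    expect_identical(back$faces, mesh$faces)
  }
})
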