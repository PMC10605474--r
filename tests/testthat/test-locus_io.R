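test_that("locus_spec validates geometry and derives the reference distance", {
  loc <- locus_spec("chr4", 39343732, 39350590, motif_length_bp = 5)
  expect_equal(loc$reference_distance_bp, 6858)
  expect_error(locus_spec("chr4", 100, 100, 5), class = "ogmstr_validation")
  expect_error(locus_spec("chr4", 100, 200, 0), class = "ogmstr_validation")
  expect_equal(parse_locus("chr4:39343732-39350590", 5)$reference_distance_bp,
               6858)
  expect_error(parse_locus("chr4;1-2", 5), class = "ogmstr_validation")
})

test_that("read_cmap parses maps, drops sentinel rows, reports format errors", {
  f <- write_lines_tmp(cmap_fixture_lines(c(
    "1\t20000.0\t3\t1\t1\t100.0",
    "1\t20000.0\t3\t2\t1\t6958.0",
    "1\t20000.0\t3\t3\t1\t20000.0",
    "1\t20000.0\t3\t4\t0\t20000.0"
  )))
  maps <- read_cmap(f)
  expect_length(maps, 1L)
  expect_equal(maps[[1]]$map_id, "1")
  expect_equal(maps[[1]]$positions$site_id, 1:3)
  expect_equal(maps[[1]]$positions$position_bp, c(100, 6958, 20000))
  expect_equal(maps[[1]]$length_bp, 20000)

  two <- write_lines_tmp(cmap_fixture_lines(c(
    "7\t5000.0\t1\t1\t1\t100.0",
    "9\t6000.0\t1\t1\t1\t200.0"
  )))
  expect_length(read_cmap(two), 2L)

  empty <- write_lines_tmp(cmap_fixture_lines(character(0)))
  expect_error(read_cmap(empty), class = "ogmstr_empty_input")

  bad <- write_lines_tmp(c("#h CMapId\tContigLength\tSiteID", "1\t10\t1"))
  expect_error(read_cmap(bad), regexp = "Position",
               class = "ogmstr_format")
})

test_that("read_xmap parses alignment pair strings and flags malformed ones", {
  f <- write_lines_tmp(xmap_fixture_lines(c(
    "1\t101\t1\t+\t15.0\t(1,1)(2,2)(3,3)",
    "2\t102\t1\t-\t12.5\t(7723,12)(7724,13)"
  )))
  alns <- read_xmap(f)
  expect_length(alns, 2L)
  expect_equal(alns[[1]]$pairs[, "ref_site"], c(1L, 2L, 3L))
  expect_equal(alns[[1]]$pairs[, "qry_site"], c(1L, 2L, 3L))
  expect_equal(alns[[2]]$orientation, "-")
  expect_equal(alns[[2]]$pairs[, "qry_site"], c(12L, 13L))
  expect_equal(alns[[2]]$confidence, 12.5)

  bad <- write_lines_tmp(xmap_fixture_lines("3\t103\t1\t+\t10.0\t(1,1)(2,"))
  expect_error(read_xmap(bad), regexp = "3", class = "ogmstr_parse")
})

test_that("extraction collects distances only from molecules spanning both markers", {
  locus <- rfc1_locus()
  ref <- make_label_map(1, c(7722, 7723, 7724, 7725),
                        c(39340000, 39343732, 39350590, 39355000))

  # molecule whose query labels sit exactly at the reference marker positions
  q1 <- make_label_map(101, 1:2, c(39343732, 39350590))
  a1 <- make_alignment(101, 1, c(7723, 1, 7724, 2))
  # negative-orientation molecule: query positions 20000 / 8557
  q2 <- make_label_map(102, 1:2, c(8557, 20000))
  a2 <- make_alignment(102, 1, c(7723, 2, 7724, 1), orientation = "-")
  # spans only the left marker -> excluded
  q3 <- make_label_map(103, 1, 500)
  a3 <- make_alignment(103, 1, c(7722, 1, 7723, 1))

  ds <- extract_intermarker_distances(list(a1, a2, a3), ref,
                                      list(q1, q2, q3), locus, "s1")
  expect_equal(ds$molecule_ids, c("101", "102"))
  expect_equal(ds$distances_bp, c(6858, 11443))
  expect_lte(length(ds$distances_bp), 3L)
  expect_true(all(ds$distances_bp > 0))
})

test_that("extraction resolves markers by position, averages split matches, errors on inconsistency", {
  locus <- locus_spec("chr4", 39343732, 39350590, 5)  # no marker ids
  ref <- make_label_map(1, 1:4, c(39340000, 39343700, 39350600, 39355000))
  q <- make_label_map(201, 1:3, c(1000, 1500, 8000))
  # left marker matched by two query sites -> mean(1000, 1500) = 1250
  a <- make_alignment(201, 1, c(2, 1, 2, 2, 3, 3))
  ds <- extract_intermarker_distances(list(a), ref, list(q), locus, "s2")
  expect_equal(ds$distances_bp, 8000 - 1250)
  expect_equal(attr(ds, "split_matches"), "201")

  # locus position too far from any reference label
  far <- locus_spec("chr4", 39000000, 39350590, 5)
  expect_error(extract_intermarker_distances(list(a), ref, list(q), far, "s"),
               class = "ogmstr_consistency")

  # alignment references a molecule missing from the query maps
  expect_error(extract_intermarker_distances(list(a), ref, list(), locus, "s"),
               class = "ogmstr_consistency")

  # nothing spans both markers -> empty set plus warning
  only_left <- make_alignment(201, 1, c(2, 1))
  expect_warning(
    empty <- extract_intermarker_distances(list(only_left), ref, list(q),
                                           locus, "s3"),
    class = "ogmstr_no_spanning_molecules"
  )
  expect_length(empty$distances_bp, 0L)
})

test_that("distance table round-trips and validates", {
  sets <- list(distance_set("a", c(6858.123, 7000.456, 9999.999)),
               distance_set("b", c(10178.5, 10508.25, 12000)))
  f <- tempfile(fileext = ".tsv")
  write_distance_table(sets, f)
  back <- read_distance_table(f)
  expect_length(back, 2L)
  expect_equal(back[[1]]$sample_id, "a")
  expect_equal(back[[1]]$distances_bp, sets[[1]]$distances_bp,
               tolerance = 1e-9)
  expect_equal(back[[2]]$distances_bp, sets[[2]]$distances_bp,
               tolerance = 1e-9)

  bad <- write_lines_tmp(c("sample_id\tmolecule_id\tdistance_bp",
                           "a\t1\t6858", "a\t2\t-5"))
  expect_error(read_distance_table(bad), regexp = "line 3",
               class = "ogmstr_validation")

  headeronly <- write_lines_tmp("sample_id\tmolecule_id\tdistance_bp")
  expect_error(read_distance_table(headeronly), class = "ogmstr_empty_input")
})

test_that("mirroring a molecule's label map leaves its distance unchanged", {
  locus <- rfc1_locus()
  set.seed(11)
  for (rep in 1:10) {
    d <- runif(1, 7000, 30000)
    ds <- distance_set("m", d, "55")
    prefix_f <- tempfile()
    # fixture writer alternates orientations; molecule 1 is "+", write a
    # second copy to get the "-" version of the same distance
    ds2 <- distance_set("m", c(d, d), c("55", "56"))
    paths <- write_alignment_fixture(ds2, locus, prefix_f)
    got <- extract_intermarker_distances(read_xmap(paths$xmap),
                                         read_cmap(paths$ref_cmap)[[1]],
                                         read_cmap(paths$qry_cmap),
                                         locus, "m")
    expect_equal(got$distances_bp[1], got$distances_bp[2], tolerance = 1e-6)
    expect_equal(got$distances_bp[1], d, tolerance = 1e-3)
  }
})
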