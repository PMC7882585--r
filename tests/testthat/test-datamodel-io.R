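test_that("community matrix CSV read-back preserves counts and labels", {
  m <- rbind(a = c(3, 0), b = c(0, 5))
  colnames(m) <- c("sp1", "sp2")
  path <- withr::local_tempfile(fileext = ".csv")
  write_cm_csv(m, path)
  cm <- suppressMessages(read_community_matrix(path))
  expect_identical(unname(site_totals(cm)), c(3, 5))
  expect_identical(site_ids(cm), c("a", "b"))
  expect_equal(unclass(cm), m, ignore_attr = TRUE)
})

test_that("species-rows orientation reads as the transpose of sites-rows", {
  set.seed(11)
  m <- matrix(rpois(12, 4) + 1, 3, 4,
              dimnames = list(paste0("s", 1:3), paste0("sp", 1:4)))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_cm_csv(m, p1)
  write_cm_csv(t(m), p2, sep = "\t")  # tab-delimited, species as rows
  direct <- suppressMessages(read_community_matrix(p1))
  transposed <- suppressMessages(read_community_matrix(p2, orientation = "species-rows"))
  expect_equal(unclass(direct), unclass(transposed))
})

test_that("malformed and invalid community files are rejected with named errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site_id,sp1,sp1", "a,1,2", "b,3,4"), path)
  expect_error(suppressMessages(read_community_matrix(path)), "Duplicate species")
  writeLines(c("site_id,sp1,sp2", "a,1,-2", "b,3,4"), path)
  expect_error(suppressMessages(read_community_matrix(path)), "non-negative")
  writeLines(c("site_id,sp1,sp2", "a,1,x", "b,3,4"), path)
  expect_error(suppressMessages(read_community_matrix(path)))
  expect_error(read_community_matrix(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("validation rejects constructed violations across table types", {
  expect_error(community_matrix(rbind(c(1, 0), c(0, 0))), "no individuals")
  expect_error(community_matrix(rbind(c(1.5, 0), c(0, 2))), "integers")
  lt <- tibble::tibble(site_id = "a", radius_m = 200, forest = 0.8, reed = 0.3,
                       grassland = 0, water = 0, agriculture = 0,
                       urban_industrial = 0, edge_length_m = 10,
                       dist_to_edge_m = 1, dist_to_canal_m = 1,
                       dist_to_industry_m = 1)
  expect_error(validate_landscape_table(lt, radii = 200), "sum to > 1")
  pcq <- tibble::tibble(site_id = "a", point_index = 1, quarter_index = 1:3,
                        distance_m = 1, tree_species_id = "t", dbh_cm = 10,
                        is_conifer = FALSE, is_dead = FALSE)
  expect_error(validate_pcq_records(pcq), "4 quarters")
  ell <- tibble::tibble(plant_species_id = "p1", humidity = 14,
                        nutrients = 4, temperature = 5)
  inc <- matrix(1, 1, 1, dimnames = list("s1", "p1"))
  tr <- tibble::tibble(plant_species_id = "p1", h = 1)
  expect_error(plant_data(inc, tr, ell), "1-12")
})

test_that("all-zero species columns are flagged but retained", {
  m <- rbind(s1 = c(2, 0, 1), s2 = c(1, 0, 3))
  colnames(m) <- paste0("sp", 1:3)
  expect_message(cm <- community_matrix(m), "all-zero")
  expect_identical(attr(cm, "empty_species"), "sp2")
  expect_identical(ncol(cm), 3L)
})

test_that("align_tables canonicalises order, drops mismatches, errors on disjoint sets", {
  cm <- tiny_cm()
  env <- tibble::tibble(site_id = c("s3", "s1", "s4", "s2"), x = 1:4)
  al <- align_tables(cm, env)
  expect_identical(site_ids(al$cm), sort(site_ids(cm)))
  expect_identical(al$env$site_id, sort(site_ids(cm)))
  expect_equal(al$env$x, c(2, 4, 1, 3))

  env2 <- env[env$site_id != "s2", ]
  expect_warning(al2 <- align_tables(cm, env2), "s2")
  expect_identical(site_ids(al2$cm), c("s1", "s3", "s4"))

  env3 <- tibble::tibble(site_id = c("z1", "z2"), x = 1:2)
  expect_error(align_tables(cm, env3), "No sites in common")
})

test_that("write_results is deterministic and handles an empty table set", {
  tabs <- list(part = tibble::tibble(site = c("a", "b", "c"), val = c(1.5, 2, 3)))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_results(tabs, d1, seed = 5, config = list(x = 1))
  write_results(tabs, d2, seed = 5, config = list(x = 1))
  expect_identical(readLines(file.path(d1, "part.csv")),
                   readLines(file.path(d2, "part.csv")))
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(man$files$part$rows, 3)

  d3 <- withr::local_tempdir()
  write_results(list(), d3)
  expect_identical(list.files(d3), "manifest.json")
})

test_that("round-trip through CSV is the identity for community tables", {
  cm <- random_cm(6, 10, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cm_csv(unclass(cm), path)
  back <- suppressMessages(read_community_matrix(path))
  expect_equal(unclass(back), unclass(cm))
})

test_that("species_overlap reports shared and exclusive species", {
  m <- rbind(a1 = c(1, 1, 1, 0), a2 = c(2, 1, 0, 0),
             b1 = c(0, 3, 1, 1), b2 = c(0, 1, 0, 2))
  colnames(m) <- paste0("sp", 1:4)
  cm <- suppressMessages(community_matrix(m, group = c("A", "A", "B", "B")))
  ov <- species_overlap(cm)
  expect_equal(ov$n_species, 4)
  expect_equal(ov$n_shared, 2)       # sp2, sp3
  expect_equal(ov$exclusive_a, 1)    # sp1
  expect_equal(ov$exclusive_b, 1)    # sp4
  expect_equal(ov$richness_a, 3)
  expect_equal(ov$shared_pct, 50)
})
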