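test_that("gut-content records parse, rescale and validate", {
  p <- withr::local_tempfile(fileext = ".csv")
  write_toy_records(p)
  rec <- read_gut_contents(p)
  expect_s3_class(rec, "gut_records")
  expect_equal(nrow(rec), 5)
  expect_equal(length(unique(rec$individual_id)), 3)

  # declared percentages are rescaled to fractions
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_toy_records(p2, percent = TRUE)
  rec2 <- read_gut_contents(p2, dialect = list(percent = TRUE))
  expect_equal(rec2$value, rec$value)

  # schema errors name the offending column
  df <- data.frame(individual_id = "i", species = "s", location = "l",
                   value = 1)
  p3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, p3, row.names = FALSE)
  expect_error(read_gut_contents(p3), "prey_item")

  # degenerate inputs
  p4 <- withr::local_tempfile(fileext = ".csv")
  file.create(p4)
  expect_error(read_gut_contents(p4), "empty")
  df$prey_item <- "x"; df$value <- -0.1
  p5 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, p5, row.names = FALSE)
  expect_error(read_gut_contents(p5), "negative")
})

test_that("crosswalk maps, splits and discards prey labels", {
  xw <- toy_crosswalk()
  rec <- gut_records(data.frame(
    individual_id = "i1", species = "spA", location = "loc1",
    prey_item = c("Algae & Detritus", "shrimp", "unidentified fragments"),
    value = c(0.40, 0.50, 0.10)))
  out <- suppressMessages(apply_crosswalk(rec, xw))
  # the composite item is equally divided between its two groups
  expect_equal(out$value[out$prey_item == "detritus"], 0.20)
  expect_equal(out$value[out$prey_item == "benthic autotroph"], 0.20)
  expect_equal(out$value[out$prey_item == "Decapoda"], 0.50)
  expect_false("unidentified fragments" %in% out$prey_item)
  # total value conserved apart from the explicit discard
  expect_equal(sum(out$value), sum(rec$value) - 0.10)

  rec2 <- gut_records(data.frame(individual_id = "i", species = "s",
                                 location = "l", prey_item = "mystery",
                                 value = 0.5))
  expect_error(apply_crosswalk(rec2, xw), "mystery")

  # crosswalks cannot invent prey groups or break split weights
  expect_error(prey_crosswalk(data.frame(label = "x", group = "not a group")),
               "canonical")
  expect_error(prey_crosswalk(data.frame(label = "x",
                                         group = c("detritus", "Decapoda"),
                                         weight = c(0.5, 0.6))),
               "sum to 1")
})

test_that("min-guts filter keeps only well-sampled species", {
  rec <- gut_records(data.frame(
    individual_id = c(paste0("a", 1:12), paste0("b", 1:9)),
    species = rep(c("spA", "spB"), c(12, 9)),
    location = "loc1", prey_item = "Decapoda", value = 1))
  out <- suppressMessages(filter_min_guts(rec, 10))
  expect_equal(unique(out$species), "spA")
  expect_equal(suppressMessages(filter_min_guts(rec, 1)),
               rec, ignore_attr = TRUE)
  expect_warning(filter_min_guts(rec, 50), "no species")
})

test_that("diet matrix averages renormalized individual profiles", {
  rec <- gut_records(data.frame(
    individual_id = c("i1", "i2", "i2"),
    species = "spA", location = "loc1",
    prey_item = c("Decapoda", "Decapoda", "Actinopterygii"),
    value = c(1.0, 0.5, 0.5)))
  diet <- build_diet_matrix(rec)
  expect_equal(unname(diet["spA", "Decapoda"]), 0.75)
  expect_equal(unname(diet["spA", "Actinopterygii"]), 0.25)
  expect_equal(unname(rowSums(diet)), 1)

  # by-location keying yields one row per species x location
  rec2 <- gut_records(data.frame(
    individual_id = c("i1", "i2"), species = "spA",
    location = c("loc1", "loc2"), prey_item = "Decapoda", value = 1))
  d2 <- build_diet_matrix(rec2, by_location = TRUE)
  expect_equal(nrow(d2), 2)
  expect_equal(attr(d2, "species"), c("spA", "spA"))

  # round trip through CSV is value-identical
  p <- withr::local_tempfile(fileext = ".csv")
  write_diet_matrix(d2, p)
  d3 <- read_diet_matrix(p)
  expect_equal(unclass(d3), unclass(d2), ignore_attr = TRUE)
  expect_equal(attr(d3, "n_guts"), attr(d2, "n_guts"))
})

test_that("tree I/O preserves patristic distances under pruning", {
  p <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", p)
  tr <- read_tree(p)
  expect_equal(length(tr$tip.label), 3)
  D <- ape::cophenetic.phylo(tr)
  expect_equal(D["A", "B"], 2)
  pruned <- prune_to(tr, c("A", "C"))
  expect_equal(ape::cophenetic.phylo(pruned)["A", "C"], D["A", "C"])
  expect_error(prune_to(tr, c("A", "Z")), "Z")
  p2 <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1", p2)
  expect_error(suppressWarnings(read_tree(p2)))
  # multi-tree files give a list
  p3 <- withr::local_tempfile(fileext = ".nwk")
  writeLines(c("((A:1,B:1):1,C:2);", "((A:2,C:2):1,B:3);"), p3)
  expect_length(read_trees(p3), 2)
})

test_that("gut record round trip is value-identical", {
  p <- withr::local_tempfile(fileext = ".csv")
  df <- write_toy_records(p)
  rec <- read_gut_contents(p)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_gut_contents(rec, p2)
  expect_equal(as.data.frame(read_gut_contents(p2)), as.data.frame(rec))
})
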