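test_that("synapse filters remove unproofread rows, then low counts", {
  tab <- data.frame(
    pre_type = "C2", pre_cell_id = "C2_01", post_type = c("A", "B", "C", "D"),
    post_cell_id = c("a1", "b1", "c1", "d1"),
    n_synapses = c(2, 3, 10, 50), proofread = c(TRUE, TRUE, TRUE, NA))
  out <- filter_synapse_table(tab)
  expect_equal(out$n_synapses, c(3, 10))            # 2 dropped, NA dropped
  expect_equal(unname(attr(out, "n_removed")), c(1, 1))
  # empty in, empty out
  expect_equal(nrow(filter_synapse_table(tab[0, ])), 0)
  # all rows unproofread -> empty with the count recorded
  allna <- tab; allna$proofread <- NA
  out2 <- filter_synapse_table(allna)
  expect_equal(nrow(out2), 0)
  expect_equal(unname(attr(out2, "n_removed")["unproofread"]), 4L)
  # malformed counts name the row
  bad <- tab; bad$n_synapses[2] <- -1
  expect_error(filter_synapse_table(bad), "row\\(s\\) 2")
  # filters commute with row permutation (same retained set)
  set.seed(1)
  perm <- tab[sample(nrow(tab)), ]
  expect_setequal(filter_synapse_table(perm)$post_cell_id, out$post_cell_id)
})

test_that("partner percentages: budgets, display filter, scale invariance", {
  # one C2 cell with outputs 60/40
  tab <- data.frame(pre_type = "C2", pre_cell_id = "C2_01",
                    post_type = c("Mi1", "Tm1"),
                    post_cell_id = c("m1", "t1"),
                    n_synapses = c(60, 40), proofread = TRUE)
  pct <- partner_percentages(tab, "C2", "output")
  expect_equal(pct$display$mean_percent[pct$display$partner_type == "Mi1"], 60)
  expect_equal(pct$display$mean_percent[pct$display$partner_type == "Tm1"], 40)
  # percentages per cell sum to 100 over all partners
  expect_equal(unname(rowSums(pct$per_cell)), 100)
  # doubling all counts changes nothing
  tab2 <- tab; tab2$n_synapses <- tab2$n_synapses * 2
  expect_equal(partner_percentages(tab2, "C2", "output")$display,
               pct$display)
  # partner in 1 of 2 cells with min_cell_fraction 0.7: hidden from the
  # display but kept in the normalization
  tab3 <- rbind(tab,
                data.frame(pre_type = "C2", pre_cell_id = "C2_02",
                           post_type = c("Mi1", "Rare"),
                           post_cell_id = c("m2", "r1"),
                           n_synapses = c(50, 50), proofread = TRUE))
  pct3 <- partner_percentages(tab3, "C2", "output", min_cell_fraction = 0.7)
  expect_false("Rare" %in% pct3$display$partner_type)
  expect_true("Rare" %in% pct3$all_partners$partner_type)
  expect_equal(unname(rowSums(pct3$per_cell)), c(100, 100))
  # cell 2's Mi1 percentage is 50 (Rare still in its denominator)
  expect_equal(unname(pct3$per_cell["C2_02", "Mi1"]), 50)
  expect_error(partner_percentages(tab, "Nope", "output"), "Nope")
})

test_that("fixture round trip returns the planted percentages exactly", {
  spec <- c(Mi1 = 50, Tm1 = 50)
  tab <- make_synapse_fixture(partners = spec, n_reference_cells = 2,
                              scale = 1, seed = 2)
  out <- partner_percentages(filter_synapse_table(tab), "C2", "output")
  got <- stats::setNames(out$display$mean_percent, out$display$partner_type)
  expect_equal(got[names(spec)], spec, tolerance = 1e-9)
  # planted sub-threshold and unproofread partners never appear
  expect_false(any(c("WeakPartner", "UnproofedPartner") %in%
                     out$all_partners$partner_type))
  # uneven spec survives the round trip up to integer rounding
  spec2 <- c(Mi1 = 41, Tm1 = 34, L5 = 25)
  tab2 <- make_synapse_fixture(partners = spec2, n_reference_cells = 3,
                               seed = 3)
  out2 <- partner_percentages(filter_synapse_table(tab2), "C2", "output")
  got2 <- stats::setNames(out2$display$mean_percent,
                          out2$display$partner_type)
  expect_equal(got2[names(spec2)], spec2, tolerance = 0.5)
  # input-direction fixture works symmetrically
  tin <- make_synapse_fixture(partners = spec, n_reference_cells = 2,
                              direction = "input", seed = 4)
  oin <- partner_percentages(filter_synapse_table(tin), "C2", "input")
  expect_equal(sort(oin$display$mean_percent), c(50, 50))
  expect_error(make_synapse_fixture(partners = c(A = 60, B = 30)),
               "sum to 100")
})

test_that("synapse CSV round trip preserves the schema", {
  tab <- make_synapse_fixture(seed = 5)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  utils::write.csv(tab, path, row.names = FALSE)
  back <- read_synapse_csv(path)
  expect_equal(back$n_synapses, tab$n_synapses)
  expect_equal(back$proofread, tab$proofread)
  expect_error(read_synapse_csv({
    p <- tempfile(fileext = ".csv")
    utils::write.csv(data.frame(a = 1), p, row.names = FALSE)
    p
  }), "missing columns")
})
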