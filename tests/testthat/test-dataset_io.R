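test_that("loader groups samples by island, sorts by day, drops absent taxa", {
  dir <- withr::local_tempdir()
  tab <- data.frame(taxon_id = c("a", "b", "c", "z"),
                    s1 = c(5L, 0L, 2L, 0L), s2 = c(0L, 3L, 1L, 0L),
                    s3 = c(1L, 1L, 0L, 0L), s4 = c(0L, 2L, 0L, 0L))
  md <- data.frame(sample_id = c("s3", "s1", "s2", "s4"),
                   island_id = c("B", "A", "A", "B"),
                   day = c(40L, 10L, 30L, 5L),
                   area_cm2 = c(200, 100, 100, 200),
                   volume_ml = c(900, 400, 400, 900))
  write.table(tab, file.path(dir, "tab.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(md, file.path(dir, "md.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  arch <- read_archipelago(file.path(dir, "tab.tsv"),
                           file.path(dir, "md.tsv"))

  expect_named(arch$islands, c("B", "A"), ignore.order = TRUE)
  # island B samples reordered by day: s4 (day 5) before s3 (day 40)
  expect_equal(arch$islands$B$census_days, c(0L, 35L))
  expect_true(arch$islands$B$presence["b", 1L])
  # all-zero taxon z dropped everywhere; c absent from island B
  expect_false("z" %in% arch$regional_pool)
  expect_false("c" %in% arch$islands$B$taxon_ids)
  # regional pool is the union; occurrence_freq counts dataset-wide samples
  expect_equal(arch$regional_pool, c("a", "b", "c"))
  expect_equal(unname(arch$occurrence_freq[c("a", "b", "c")]),
               c(2L, 3L, 2L))
  expect_equal(sum(arch$occurrence_freq),
               sum(vapply(arch$islands, function(ts) sum(ts$presence), 0)))
})

test_that("loader rejects malformed inputs", {
  dir <- withr::local_tempdir()
  tabp <- file.path(dir, "tab.tsv"); mdp <- file.path(dir, "md.tsv")
  tab <- data.frame(taxon_id = c("a", "b"), s1 = c(1L, 2L), s2 = c(2L, 1L),
                    s3 = c(1L, 1L))
  md <- data.frame(sample_id = c("s1", "s2", "s3"), island_id = "A",
                   day = c(0L, 10L, 20L), area_cm2 = 100, volume_ml = 400)
  wr <- function(tb, mm) {
    write.table(tb, tabp, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(mm, mdp, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(tab, transform(md, sample_id = c("s1", "s2", "sX")))
  expect_error(read_archipelago(tabp, mdp), "unknown sample")
  wr(tab, transform(md, day = c(0L, 10L, 10L)))
  expect_error(read_archipelago(tabp, mdp), "duplicate")
  tab2 <- tab; tab2$s2[1] <- -3L
  wr(tab2, md)
  expect_error(read_archipelago(tabp, mdp), "negative")
  tab3 <- tab; tab3$s2 <- 0L
  wr(tab3, md)
  expect_error(read_archipelago(tabp, mdp), "zero observed taxa")
})

test_that("write/read round-trip reproduces presence matrices exactly", {
  arch <- small_archipelago(seed = 7)
  dir <- withr::local_tempdir()
  paths <- write_archipelago(arch, dir)
  back <- read_archipelago(paths["taxon_table"], paths["metadata"])
  expect_setequal(names(back$islands), names(arch$islands))
  for (isl in names(arch$islands)) {
    a <- arch$islands[[isl]]; b <- back$islands[[isl]]
    expect_equal(b$census_days, a$census_days)
    expect_equal(b$presence[a$taxon_ids, ], a$presence)
  }
  expect_equal(back$regional_pool, arch$regional_pool)
  expect_equal(back$occurrence_freq, arch$occurrence_freq)
})

test_that("regional pool and occurrence_freq are permutation invariant", {
  dir <- withr::local_tempdir()
  tab <- data.frame(taxon_id = c("a", "b", "c"),
                    s1 = c(1L, 1L, 0L), s2 = c(0L, 1L, 1L),
                    s3 = c(1L, 0L, 1L), s4 = c(1L, 1L, 1L))
  md <- data.frame(sample_id = paste0("s", 1:4),
                   island_id = c("A", "A", "B", "B"),
                   day = c(0L, 10L, 0L, 10L), area_cm2 = 100,
                   volume_ml = 400)
  wr <- function(tb, mm, tag) {
    tp <- file.path(dir, paste0("t", tag, ".tsv"))
    mp <- file.path(dir, paste0("m", tag, ".tsv"))
    write.table(tb, tp, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(mm, mp, sep = "\t", quote = FALSE, row.names = FALSE)
    read_archipelago(tp, mp)
  }
  a1 <- wr(tab, md, 1)
  perm <- tab[c(3, 1, 2), c("taxon_id", "s4", "s2", "s1", "s3")]
  a2 <- wr(perm, md[c(2, 4, 1, 3), ], 2)
  expect_equal(a2$regional_pool, a1$regional_pool)
  expect_equal(a2$occurrence_freq, a1$occurrence_freq)
})

test_that("write_results is deterministic and handles empty tables", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  empty <- data.frame(island_id = character(0), w = numeric(0))
  tabs <- list(fits = data.frame(island_id = "A", w = 1 / 3),
               empty = empty)
  info <- list(seed = 1L, n_rand = 10L)
  write_results(tabs, d1, run_info = info)
  write_results(tabs, d2, run_info = info)
  for (f in c("fits.tsv", "empty.tsv", "run_summary.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_equal(readLines(file.path(d1, "empty.tsv")), "island_id\tw")
})
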