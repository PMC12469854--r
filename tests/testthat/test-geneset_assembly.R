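test_that("load_source applies the per-source curation filters", {
  lmap <- data.frame(gene = c("A", "B", "C"),
                     Association = c("significant", "non-significant",
                                     "Significant"))
  got <- load_source(lmap, "longevitymap",
                     source_rules("gene", "Association"))
  expect_setequal(got$gene_label, c("A", "C"))   # case-insensitive match

  ca <- data.frame(gene = c("A", "B", "C"),
                   `Senescence Effect` = c("Induces", "Inhibits", "Unclear"),
                   check.names = FALSE)
  got <- load_source(ca, "cellage", source_rules("gene", "Senescence Effect"))
  expect_setequal(got$gene_label, c("A", "B"))

  de <- data.frame(gene = c("A", "B", "C"), logFC = c(1.2, 0.8, -1.5))
  expect_setequal(
    load_source(de, "deg_gse72815", source_rules("gene", "logFC", "up"))$gene_label,
    "A")
  expect_setequal(
    load_source(de, "deg_gse72815", source_rules("gene", "logFC", "both"))$gene_label,
    c("A", "C"))
  # logFC exactly 1 is excluded (strict cutoff)
  de1 <- data.frame(gene = "X", logFC = 1)
  expect_identical(nrow(load_source(de1, "deg_gse141595",
                                    source_rules("gene", "logFC", "up"))), 0L)

  expect_error(load_source(de, "drugbank", source_rules("gene")), "unknown")
  expect_error(load_source(lmap, "cellage", source_rules("gene", "Effect")),
               "Effect")
})

test_that("assemble counts raw entries and dedups canonical labels", {
  e <- rbind(data.frame(gene_label = c("A", "B"), source_tag = "genage"),
             data.frame(gene_label = c(" b", "C"), source_tag = "cellage"),
             data.frame(gene_label = c("C", "D"), source_tag = "agingatlas"))
  asm <- assemble(e)
  expect_identical(asm$total, 6L)
  expect_identical(asm$deduplicated, c("A", "B", "C", "D"))
})

test_that("convert_ids drops unmapped labels, re-dedups and sorts", {
  mapping <- data.frame(label = c("A", "B", "C"), id = c("1", "2", "3"))
  uni <- suppressWarnings(convert_ids(c("A", "B", "D"), mapping))
  expect_identical(uni$genes, c("1", "2"))
  expect_identical(uni$n_dropped, 1L)
  expect_warning(convert_ids(c("A", "D"), mapping), "could not be converted")

  # identity mapping: |universe| = |distinct labels|
  uni2 <- convert_ids(c("b", "a", "B"))
  expect_identical(uni2$genes, c("A", "B"))

  # many-to-one mapping collapses
  m2 <- data.frame(label = c("A", "B"), id = c("X", "X"))
  expect_identical(convert_ids(c("A", "B"), m2)$genes, "X")

  m3 <- data.frame(label = c("A", "A"), id = c("1", "2"))
  expect_error(convert_ids("A", m3), "duplicate keys")

  # index is a bijection onto positions
  expect_identical(unname(uni2$index), seq_along(uni2$genes))
})

test_that("universe assembly is order-insensitive and deterministic", {
  gen <- gen_source_tables(synthetic_config(seed = 5L))
  srcs <- lapply(names(gen$tables), function(nm)
    list(path = gen$tables[[nm]], tag = nm, rules = gen$rules[[nm]]))
  r1 <- suppressWarnings(build_universe(srcs, gen$mapping))
  r2 <- suppressWarnings(build_universe(rev(srcs), gen$mapping))
  expect_identical(r1$universe$genes, r2$universe$genes)
  expect_identical(r1$universe$genes,
                   suppressWarnings(build_universe(srcs, gen$mapping))$universe$genes)
  s <- r1$summary
  expect_lte(s$after_id_conversion, s$after_dedup)
  expect_lte(s$after_dedup, s$total)
})

test_that("assembly recovers the generator's planted distinct/mappable counts", {
  gen <- gen_source_tables(synthetic_config(seed = 9L))
  srcs <- lapply(names(gen$tables), function(nm)
    list(path = gen$tables[[nm]], tag = nm, rules = gen$rules[[nm]]))
  res <- suppressWarnings(build_universe(srcs, gen$mapping))
  expect_identical(res$summary$after_dedup, gen$truth$n_distinct)
  expect_identical(res$summary$after_id_conversion, gen$truth$n_mappable)

  # no duplication: per-source totals equal kept distinct rows per source
  gen0 <- gen_source_tables(synthetic_config(seed = 9L, duplication_rate = 0))
  srcs0 <- lapply(names(gen0$tables), function(nm)
    list(path = gen0$tables[[nm]], tag = nm, rules = gen0$rules[[nm]]))
  loaded <- lapply(srcs0, function(s) load_source(s$path, s$tag, s$rules))
  asm <- assemble(loaded)
  per_source_distinct <- sum(vapply(loaded, function(df)
    length(unique(canonicalize_gene(df$gene_label))), 0L))
  expect_identical(asm$total, per_source_distinct)

  # fully unmappable labels: empty universe, everything dropped
  gen1 <- gen_source_tables(synthetic_config(seed = 9L,
                                             unmappable_fraction = 1))
  res1 <- suppressWarnings(build_universe(
    lapply(names(gen1$tables), function(nm)
      list(path = gen1$tables[[nm]], tag = nm, rules = gen1$rules[[nm]])),
    gen1$mapping))
  expect_identical(res1$summary$after_id_conversion, 0L)
  expect_identical(res1$universe$n_dropped, gen1$truth$n_distinct)
})

test_that("universe writes and re-reads byte-identically", {
  gen <- gen_source_tables(synthetic_config(seed = 2L))
  res <- suppressWarnings(
    build_universe(list(list(path = gen$tables$genage, tag = "genage",
                             rules = gen$rules$genage)), gen$mapping))
  f <- withr::local_tempfile()
  write_universe(res, f)
  expect_identical(read_universe(f)$genes, res$universe$genes)
})
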