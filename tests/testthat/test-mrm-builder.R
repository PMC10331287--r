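test_that("precursor m/z follows the adduct table with electron correction", {
  expect_equal(precursor_mz(764.689391, "[M+NH4]+"), 782.723216,
               tolerance = 1e-5)
  expect_equal(precursor_mz(270.255880, "[M-H]-"), 269.248604,
               tolerance = 1e-6)
  expect_error(precursor_mz(0, "[M+H]+"), "positive")
  expect_error(precursor_mz(500, "[M+Na]+"), "unknown adduct")
})

test_that("TAG neutral losses are the acid plus ammonia: 259/287/315 nominal", {
  for (case in list(list(a = "15:0", nl = 259), list(a = "17:0", nl = 287),
                    list(a = "19:0", nl = 315))) {
    sp <- lipid_species("TAG", rep(case$a, 3))
    tr <- tag_dag_transitions(sp)
    expect_equal(nrow(tr), 1)  # identical acyls merge to one channel
    expect_equal(round(tr$q1 - tr$q3), case$nl)
  }
  sp <- lipid_species("TAG", c("15:0", "15:0", "15:0"))
  tr <- tag_dag_transitions(sp)
  expect_equal(tr$q1, 782.7232, tolerance = 1e-4)
  expect_equal(tr$q3, 523.4721, tolerance = 1e-4)
  # each double bond shrinks the loss by 2 Da
  tr1 <- tag_dag_transitions(lipid_species("TAG", c("15:1", "15:1", "15:1")))
  expect_equal(round(tr1$q1 - tr1$q3), 257)
})

test_that("DAG daughters are protonated dehydrated MAGs: 299/327/355 nominal", {
  for (case in list(list(a = "15:0", q3 = 299), list(a = "17:0", q3 = 327),
                    list(a = "19:0", q3 = 355))) {
    tr <- tag_dag_transitions(lipid_species("DAG", rep(case$a, 2)))
    expect_equal(round(tr$q3), case$q3)
  }
  mixed <- tag_dag_transitions(lipid_species("DAG", c("15:0", "17:0")))
  expect_equal(nrow(mixed), 2)
  mag <- tag_dag_transitions(lipid_species("MAG", "15:0"))
  expect_equal(nrow(mag), 1)
  expect_error(tag_dag_transitions(lipid_species("PC", c("15:0", "18:1"))),
               "does not handle")
})

test_that("phospholipid products are carboxylate anions, one per distinct acyl", {
  tr <- phospholipid_transitions(lipid_species("PI", c("17:0", "18:1")))
  expect_equal(tr$q1, rep(849.5499, 2), tolerance = 1e-4)
  expect_equal(sort(tr$q3), c(269.2486, 281.2486), tolerance = 1e-4)
  # identical acyls merge; annotation covers both sn sites
  pa <- phospholipid_transitions(lipid_species("PA", c("15:0", "15:0")))
  expect_equal(nrow(pa), 1)
  expect_match(pa$fragment, "sn-1/sn-2")
  lpe <- phospholipid_transitions(lipid_species("LPE", "17:0"))
  expect_equal(nrow(lpe), 1)
  # PC rides the acetate adduct in negative mode
  pc <- phospholipid_transitions(lipid_species("PC", c("15:0", "18:1")))
  expect_equal(unique(pc$adduct), "[M+CH3COO]-")
  pc_formate <- phospholipid_transitions(lipid_species("PC", c("15:0", "18:1")),
                                         pc_adduct = "[M-H]-")
  expect_lt(unique(pc_formate$q1), unique(pc$q1))
})

test_that("sphingolipid and FFA channels use the fixed fragments", {
  sm <- sphingo_ffa_transitions(lipid_species("SM", "17:0"))
  expect_equal(sm$q3, 184.0733, tolerance = 1e-4)
  cer <- sphingo_ffa_transitions(lipid_species("Cer", "17:0"))
  expect_equal(cer$q3, 264.2686, tolerance = 1e-4)
  dh <- sphingo_ffa_transitions(lipid_species("dhCer", "17:0"))
  expect_equal(dh$q3, 266.2842, tolerance = 1e-4)
  ffa <- sphingo_ffa_transitions(lipid_species("FFA", "15:0"))
  expect_equal(ffa$q1, ffa$q3)
  expect_equal(ffa$q1, 241.2173, tolerance = 1e-4)
})

test_that("library-wide Q1/Q3 match the independent mass oracle", {
  lib <- enumerate_odd_library(library_config(
    c("TAG", "DAG", "PC", "PE", "PI", "LPE", "SM", "Cer", "FFA"),
    odd_carbons = c(15L, 17L), even_carbons = 18L, double_bonds = 0:1))
  tr <- build_transitions(lib)
  lib_nd <- lapply(strsplit(lib$acyls, "/"), acyl_nd)
  names(lib_nd) <- lib$name

  for (i in seq_len(nrow(tr))) {
    row <- tr[i, ]
    nd <- lib_nd[[row$name]]
    neutral <- oracle_species_mass(row$subclass, nd)
    q1_want <- switch(
      row$adduct,
      "[M+NH4]+" = neutral + 18.034374 - oracle_electron,
      "[M+H]+" = neutral + 1.007825 - oracle_electron,
      "[M-H]-" = neutral - 1.007825 + oracle_electron,
      "[M+CH3COO]-" = neutral + 59.013305 + oracle_electron)
    expect_equal(row$q1, q1_want, tolerance = 1e-3)
    if (row$subclass == "TAG") {
      a <- regmatches(row$fragment, regexpr("\\d+:\\d+", row$fragment))
      nd_a <- acyl_nd(a)
      nl <- oracle_fa_mass(nd_a[1], nd_a[2]) + 3 * 1.0078250319 + 14.0030740052
      expect_equal(row$q1 - row$q3, nl, tolerance = 1e-3)
    }
    if (row$subclass %in% c("PA", "PC", "PE", "PG", "PI", "PS", "LPE", "LPC")) {
      a <- regmatches(row$fragment, regexpr("\\d+:\\d+", row$fragment))
      nd_a <- acyl_nd(a)
      expect_equal(row$q3,
                   oracle_fa_mass(nd_a[1], nd_a[2]) - 1.007825 + oracle_electron,
                   tolerance = 1e-3)
    }
  }
})

test_that("transition counts per subclass match the fragmentation design", {
  lib <- enumerate_odd_library(library_config(
    c("TAG", "DAG", "PE", "LPE", "SM", "FFA"),
    odd_carbons = c(15L, 17L), even_carbons = 18L, double_bonds = 0:1))
  tr <- build_transitions(lib)
  counts <- table(tr$name)
  for (i in seq_len(nrow(lib))) {
    n <- counts[[lib$name[i]]]
    n_distinct_acyls <- length(unique(strsplit(lib$acyls[i], "/")[[1]]))
    if (lib$subclass[i] == "TAG") {
      expect_lte(n, 3); expect_equal(n, n_distinct_acyls)
    } else if (lib$subclass[i] %in% c("DAG", "PE")) {
      expect_equal(n, n_distinct_acyls); expect_lte(n, 2)
    } else {
      expect_equal(n, 1)
    }
  }
  # swapping sn labels never changes the transition set
  t1 <- phospholipid_transitions(lipid_species("PE", c("15:0", "18:1")))
  t2 <- phospholipid_transitions(lipid_species("PE", c("18:1", "15:0")))
  expect_equal(sort(t1$q3), sort(t2$q3))
})

test_that("isomer enumeration is exhaustive and duplicate-free", {
  pool <- c("13:0", "15:0", "17:0", "19:0")
  cand <- isomer_candidates("TAG", 45, 0, pool)
  expect_true("15:0/15:0/15:0" %in% cand$acyls)
  expect_true("13:0/15:0/17:0" %in% cand$acyls)
  want <- oracle_isomers(3, 45, 0, pool)
  expect_equal(sort(gsub("/", "|", cand$acyls)), want)

  # the TAG 51:3 candidate set contains 15:0-17:1-19:2
  pool2 <- acyl_pool_grid <- apply(
    expand.grid(c = c(15L, 17L, 19L, 21L), d = 0:3), 1,
    function(r) paste0(r[1], ":", r[2]))
  cand2 <- isomer_candidates("TAG", 51, 3, pool2)
  expect_true("15:0/17:1/19:2" %in% cand2$acyls)
  expect_equal(sort(gsub("/", "|", cand2$acyls)),
               oracle_isomers(3, 51, 3, pool2))

  forced <- isomer_candidates("DAG", 30, 0, "15:0")
  expect_equal(forced$acyls, "15:0/15:0")
  expect_error(isomer_candidates("DAG", 30, 0, character(0)), "empty")
})

test_that("acquisition parameters inherit from the nearest same-class IS", {
  is_panel <- tibble::tibble(
    is_id = c("IS TAG 45:0(d7)", "IS TAG 51:0(d7)", "IS PE 33:0(d7)"),
    subclass = c("TAG", "TAG", "PE"),
    total_carbons = c(45L, 51L, 33L),
    total_double_bonds = c(0L, 0L, 0L),
    ce = c(45, 47, -45), dp = c(100, 105, -90), dwell_ms = c(5, 5, 5))
  lib <- dplyr::bind_rows(
    lipid_species("TAG", c("15:0", "15:0", "15:0")),   # exact 45:0
    lipid_species("TAG", c("15:0", "15:0", "17:1")),   # 47:1 -> 45:0 nearest
    lipid_species("PG", c("15:0", "18:1")))            # no PG IS
  out <- assign_acquisition_params(lib, is_panel)
  expect_equal(out$is_id[1], "IS TAG 45:0(d7)")
  expect_equal(out$is_id[2], "IS TAG 45:0(d7)")  # |dC|=2 beats |dC|=4
  expect_false(out$parameterized[3])
  expect_true(is.na(out$ce[3]))
  expect_error(assign_acquisition_params(lib, is_panel[0, ]), "empty")
})

test_that("co-elution validation applies the RT tolerance and finds isomer doublets", {
  peaks <- tibble::tibble(
    name = c("A", "A", "B", "B", "C"),
    fragment = c("f1", "f2", "f1", "f2", "f1"),
    rt_min = c(12.31, 12.33, 12.31, 12.80, 5.0),
    sn = c(50, 50, 50, 50, 50))
  v <- validate_by_coelution(peaks, tol_min = 0.1)
  expect_equal(v$verdict[v$name == "A"], "VALIDATED")
  expect_equal(v$verdict[v$name == "B"], "NOT_VALIDATED")
  expect_equal(v$offending[v$name == "B"], "f2")
  expect_equal(v$verdict[v$name == "C"], "UNTESTABLE")

  # doublet peaks in every channel -> two isomer groups
  doublet <- tibble::tibble(
    name = "D", fragment = rep(c("f1", "f2"), 2),
    rt_min = c(12.30, 12.32, 13.10, 13.12), sn = 50)
  vd <- validate_by_coelution(doublet, tol_min = 0.1)
  expect_equal(vd$verdict, "VALIDATED")
  expect_equal(vd$n_isomer_groups, 2L)

  # low S/N fails even with co-elution
  low <- tibble::tibble(name = "E", fragment = c("f1", "f2"),
                        rt_min = c(8.0, 8.01), sn = c(50, 5))
  vl <- validate_by_coelution(low, tol_min = 0.1, sn_min = 10)
  expect_equal(vl$verdict, "NOT_VALIDATED")
  expect_match(vl$offending, "S/N")
})
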