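#' Run the full species-tree comparison protocol
#'
#' End to end: simulate (or ingest) a three-class locus set, trim heavily
#' gapped columns, filter loci by the symmetry test, infer gene trees,
#' build the dataset-by-method species-tree grid (four datasets: exon-like
#' `ncCDS`, intron-like `ncINT`, their union `ncGD`, linked plastid-like
#' `plCDS`; five methods: quartet-MSC `As`, gene+site bootstrap MSC `Abs`,
#' site-only fast-bootstrap MSC `AUFbs`, concatenated partitioned `Cpa`
#' and unpartitioned `Cun`), harmonize the 20 trees, ordinate the tree
#' landscape (RF unrooted, KC rooted) with groves, run SH/AU topology
#' tests against the fixed `ncCDS` `Cpa` tree, and tabulate gene/site
#' concordance factors for a set of focus clades.
#'
#' @param config A [sim_config], or a list of [locus_aln] to ingest.
#' @param cfg A [test_config] for the topology tests.
#' @param clades Named list of clades; `NULL` derives them from the true
#'   species tree (simulated input only).
#' @param seed Integer seed governing every stochastic stage.
#' @param gt Gap threshold for column trimming.
#' @param alpha Symmetry-test rejection level.
#' @param replicates Named list overriding bootstrap replicate counts
#'   (`Abs`, `AUFbs`, `concat`).
#' @param root_on Outgroup label for harmonization; default is the first
#'   taxon label.
#' @param q Quartets per branch for sCF.
#' @param verbose Print stage progress?
#' @return A `protocol_run` list: `trees` ([tree_collection] of 20),
#'   `summary` (per-dataset [summarize_dataset] rows), `qc_report`,
#'   `landscape` (RF and KC distance matrices, ordinations, groves),
#'   `toptest` ([compare_to_fixed] report), `cf_table`
#'   ([cf_heatmap_table]), `clades`, `gene_trees`, `supermatrices`,
#'   `species_tree` (truth, when simulated), `seed`, `config`.
#' @export
run_protocol <- function(config = sim_config(), cfg = test_config(),
                         clades = NULL, seed = 1, gt = 0.2, alpha = 0.05,
                         replicates = list(), root_on = NULL, q = 100L,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message("[", format(Sys.time(), "%H:%M:%S"),
                                            "] ", ...)
  reps <- utils::modifyList(list(Abs = 100L, AUFbs = 200L, concat = 100L),
                            replicates)
  set.seed(seed)
  truth <- NULL
  if (inherits(config, "sim_config")) {
    say("simulate: building study dataset (seed ", seed, ")")
    config$seed <- seed
    ds <- build_study_dataset(config)
    loci <- ds$loci
    truth <- ds$species_tree
  } else {
    loci <- config
    config <- NULL
  }

  say("qc: trimming gapped columns (gt = ", gt, ")")
  loci <- lapply(loci, trim_gapped_columns, gt = gt)
  say("qc: symmetry-test filtering (alpha = ", alpha, ")")
  flt <- filter_loci_symtest(loci, alpha = alpha)
  loci <- flt$kept

  class_of <- vapply(loci, function(l) attr(l, "class_tag"), character(1))
  by_class <- split(loci, class_of)
  datasets <- list(ncCDS = by_class$CDS, ncINT = by_class$INT,
                   ncGD = c(by_class$CDS, by_class$INT),
                   plCDS = by_class$PL)
  datasets <- datasets[!vapply(datasets, is.null, logical(1))]
  summary_tab <- do.call(rbind, lapply(names(datasets), function(d)
    summarize_dataset(datasets[[d]], dataset = d)))

  say("genetrees: neighbor joining per locus")
  gts_by_class <- lapply(by_class, infer_gene_trees)
  gts <- list(ncCDS = gts_by_class$CDS, ncINT = gts_by_class$INT,
              ncGD = c(gts_by_class$CDS, gts_by_class$INT),
              plCDS = gts_by_class$PL)
  gts <- gts[names(datasets)]

  supermatrices <- lapply(datasets, concat_supermatrix)

  methods <- c("As", "Abs", "AUFbs", "Cpa", "Cun")
  trees <- list(); dslab <- character(0); melab <- character(0)
  for (d in names(datasets)) {
    say("speciestree: dataset ", d)
    sub_seed <- seed + match(d, names(datasets)) * 1000L
    main <- msc_tree(gts[[d]])
    abs_tree <- msc_bootstrap(datasets[[d]], replicates = reps$Abs,
                              flavor = "gene_site", seed = sub_seed + 1L)
    ufb_tree <- msc_bootstrap(datasets[[d]], replicates = reps$AUFbs,
                              flavor = "site_only", seed = sub_seed + 2L)
    cpa <- concatenated_tree(datasets[[d]], partitioned = TRUE,
                             bootstrap = reps$concat, seed = sub_seed + 3L)
    cun <- concatenated_tree(datasets[[d]], partitioned = FALSE,
                             bootstrap = reps$concat, seed = sub_seed + 4L)
    for (tr in list(main, abs_tree, ufb_tree, cpa, cun))
      trees[[length(trees) + 1]] <- tr
    dslab <- c(dslab, rep(d, 5)); melab <- c(melab, methods)
  }
  coll <- tree_collection(trees, dslab, melab)

  if (is.null(root_on)) {
    common <- Reduce(intersect, lapply(trees, `[[`, "tip.label"))
    root_on <- sort(common)[1]
  }
  say("harmonize: rooting on ", root_on)
  common <- Reduce(intersect, lapply(trees, `[[`, "tip.label"))
  drop <- setdiff(Reduce(union, lapply(trees, `[[`, "tip.label")), common)
  harm <- harmonize_trees(unclass(coll), drop = drop, root_on = root_on)
  harm <- tree_collection(harm, dslab, melab)

  say("landscape: RF and KC ordinations")
  D_rf <- tree_distance_matrix(harm, "RF")
  D_kc <- tree_distance_matrix(harm, "KC", lambda = 0)
  ord_rf <- pcoa(D_rf, k = 3)
  ord_kc <- pcoa(D_kc, k = 3)
  landscape <- list(
    rf = list(D = D_rf, ordination = ord_rf,
              groves = find_groves(ord_rf, k_groups = 2)),
    kc = list(D = D_kc, ordination = ord_kc,
              groves = find_groves(ord_kc, k_groups = 3)))

  say("toptest: SH/AU against fixed ncCDS Cpa")
  toptest <- NULL
  if ("ncCDS" %in% names(datasets)) {
    fixed <- harm[["ncCDS_Cpa"]]
    eval_sm <- concat_supermatrix(datasets$ncCDS, taxa = fixed$tip.label)
    if (is.null(cfg$seed)) cfg$seed <- seed + 77L
    toptest <- compare_to_fixed(fixed, harm, eval_sm, cfg)
  }

  if (is.null(clades)) {
    clades <- if (!is.null(truth)) default_clades(truth, root_on)
    else default_clades(harm[[1]], root_on)
  }
  say("concord: gene/site concordance factors for ", length(clades),
      " clades")
  cf_tab <- cf_heatmap_table(harm, clades, gts, supermatrices, q = q,
                             seed = seed + 99L)

  say("done: ", length(harm), " species trees")
  structure(list(trees = harm, summary = summary_tab,
                 qc_report = flt$report, landscape = landscape,
                 toptest = toptest, cf_table = cf_tab, clades = clades,
                 gene_trees = gts, supermatrices = supermatrices,
                 species_tree = truth, loci = datasets, seed = seed,
                 config = config),
            class = "protocol_run")
}

# focus clades = the non-trivial clades of a rooted guide tree, excluding
# the outgroup side
default_clades <- function(tree, root_on) {
  tr <- tryCatch(ape::root(tree, outgroup = root_on, resolve.root = TRUE),
                 error = function(e) tree)
  sets <- edge_tip_sets(tr)
  sz <- lengths(sets)
  n <- length(tr$tip.label)
  keep <- sz >= 2 & sz <= n - 2
  sets <- unique(lapply(sets[keep], sort))
  names(sets) <- sprintf("clade%02d", seq_along(sets))
  sets
}

#' @export
print.protocol_run <- function(x, ...) {
  key <- attr(x$trees, "key")
  cat("<protocol_run> seed", x$seed, "-", length(x$trees), "species trees (",
      length(unique(key$dataset)), "datasets x",
      length(unique(key$method)), "methods )\n")
  cat("  datasets:", paste(unique(key$dataset), collapse = ", "), "\n")
  if (!is.null(x$toptest))
    cat("  topology tests: ", sum(x$toptest$AU == "-"),
        "of", nrow(x$toptest), "trees rejected by AU\n")
  invisible(x)
}

#' Write the protocol run as a report bundle
#'
#' Emits machine-readable CSVs (summary table, QC report, distance
#' matrices, ordination coordinates, grove labels, topology-test report,
#' concordance-factor long table), the 20 trees as multi-Newick, and a
#' markdown report that references every artifact.
#'
#' @param run A [run_protocol] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(dir, f)
  utils::write.csv(run$summary, pth("summary_table.csv"), row.names = FALSE)
  utils::write.csv(run$qc_report, pth("qc_report.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(unclass(run$landscape$rf$D)),
                   pth("dist_rf.csv"))
  utils::write.csv(as.data.frame(unclass(run$landscape$kc$D)),
                   pth("dist_kc.csv"))
  utils::write.csv(data.frame(tree = names(run$trees),
                              run$landscape$rf$ordination$coords,
                              grove_rf = run$landscape$rf$groves,
                              grove_kc = run$landscape$kc$groves),
                   pth("ordination.csv"), row.names = FALSE)
  if (!is.null(run$toptest))
    utils::write.csv(run$toptest, pth("topology_tests.csv"),
                     row.names = FALSE)
  utils::write.csv(run$cf_table, pth("concordance_factors.csv"),
                   row.names = FALSE)
  write_trees(unclass(run$trees), pth("species_trees.nwk"))
  if (!is.null(run$species_tree))
    write_trees(run$species_tree, pth("true_species_tree.nwk"))

  key <- attr(run$trees, "key")
  md <- c(
    "# Species-tree concordance protocol report", "",
    sprintf("Seed: %d. Trees: %d (%d datasets x %d methods).", run$seed,
            length(run$trees), length(unique(key$dataset)),
            length(unique(key$method))), "",
    "## Dataset summary (see summary_table.csv)", "",
    knit_md_table(run$summary), "",
    "## Topology tests (see topology_tests.csv)", "",
    if (!is.null(run$toptest))
      knit_md_table(run$toptest[, c("dataset", "tree", "p_SH", "SH",
                                    "p_AU", "AU")]) else "(not run)", "",
    "## Groves", "",
    paste0("- RF groves: ",
           paste(names(run$landscape$rf$groves), run$landscape$rf$groves,
                 sep = "=", collapse = ", ")),
    paste0("- KC groves: ",
           paste(names(run$landscape$kc$groves), run$landscape$kc$groves,
                 sep = "=", collapse = ", ")), "",
    "## Concordance factors",
    "See concordance_factors.csv (one row per clade x tree).", "")
  writeLines(unlist(md), pth("report.md"))
  invisible(dir)
}

knit_md_table <- function(df) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 4))
  hdr <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  rows <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
  c(hdr, sep, rows)
}
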