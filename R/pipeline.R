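#' Run the full analysis pipeline from one configuration
#'
#' Orchestrates the stages end-to-end in methods order — hard filtering,
#' ploidy estimation, exclusive-SNV sharing, gene diversity, ABBA-BABA
#' trios, phylogeny — writing every stage's table under `out_dir` plus a
#' single JSON summary. The run is fully reproducible from config + seed:
#' the global seed fans out to per-stage seeds through a fixed derivation,
#' so each stage is individually repeatable and disabling one stage never
#' changes another's outputs.
#'
#' @param config a YAML path or a list with elements: `vcf`,
#'   `sample_sheet`, `out_dir`, `seed`, and optionally `reference`
#'   (required for the phylogeny stage), `repeats`, `genes`, `outgroup`
#'   (group label for the introgression stage), `stages` (named logical
#'   list: filter, ploidy, sharing, diversity, dstat, phylogeny),
#'   `params` (genome_length, window, bandwidth, n_blocks, bootstrap,
#'   chroms, totals, threshold overrides `snv` / `indel`).
#' @return list of stage results (also serialized to
#'   `out_dir/summary.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_run_config(config)
  stages <- cfg$stages
  params <- cfg$params
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop2("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  sheet <- read_sample_sheet(cfg$sample_sheet)
  x <- read_vcf(cfg$vcf, sheet)
  repeats <- if (!is.null(cfg$repeats))
    read_intervals(cfg$repeats, "bed", "repeat") else NULL
  genes <- if (!is.null(cfg$genes))
    read_intervals(cfg$genes, "gff3", "gene") else NULL
  genome_length <- params$genome_length %||% NULL

  summary <- list(seed = cfg$seed, n_input_sites = n_sites(x),
                  samples = x$samples)
  results <- list()
  thresholds <- filter_thresholds(snv = params$snv %||% list(),
                                  indel = params$indel %||% list())

  # --- filter ---------------------------------------------------------
  if (isTRUE(stages$filter)) {
    results$filter <- run_stage("filter", {
      fs <- filter_snvs(x, thresholds)
      fi <- filter_indels(x, thresholds)
      write_vcf(fs$variants, file.path(cfg$out_dir, "filtered_snvs.vcf"))
      fs$report$mode <- rep("snv", nrow(fs$report))
      fi$report$mode <- rep("indel", nrow(fi$report))
      rep_tab <- rbind(fs$report, fi$report)
      write.table(rep_tab, file.path(cfg$out_dir, "filter_report.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      ind_sum <- summarize_indels(fi$variants, genes)
      list(snv = fs, indel = fi, indel_summary = ind_sum)
    })
    snvs <- results$filter$snv$variants
    summary$filter <- list(snv_in = results$filter$snv$n_input,
                           snv_pass = results$filter$snv$n_pass,
                           indel_in = results$filter$indel$n_input,
                           indel_pass = results$filter$indel$n_pass)
  } else {
    snvs <- x[which(is_snv(x) & n_alt(x) == 1L), ]
  }
  if (!is.null(genome_length)) {
    dens <- snv_density(snvs, genome_length)
    write.table(dens, file.path(cfg$out_dir, "snv_density.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- ploidy ---------------------------------------------------------
  if (isTRUE(stages$ploidy)) {
    results$ploidy <- run_stage("ploidy", {
      lapply(setNames(nm = snvs$samples), function(s) {
        prof <- allele_balance_profile(snvs, s, chroms = params$chroms)
        if (nrow(prof) == 0)
          return(list(ploidy = NA, n_het = 0, low_balance = NULL))
        modes <- detect_modes(prof, bandwidth = params$bandwidth %||% 0.02)
        call <- call_ploidy(modes)
        lb <- classify_low_balance(
          prof, window = params$window %||% c(0.05, 0.25),
          repeats = repeats, genes = genes)
        list(ploidy = call$ploidy, n_het = nrow(prof),
             modes = modes$position, secondary = call$secondary_mode,
             low_balance = lb)
      })
    })
    ploidy_tab <- data.frame(
      sample = names(results$ploidy),
      called_ploidy = vapply(results$ploidy, function(r)
        as.numeric(r$ploidy %||% NA), numeric(1)),
      n_het_sites = vapply(results$ploidy, function(r)
        as.numeric(r$n_het), numeric(1)))
    write.table(ploidy_tab, file.path(cfg$out_dir, "ploidy_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    summary$ploidy <- setNames(as.list(ploidy_tab$called_ploidy),
                               ploidy_tab$sample)
  }

  groups <- split(sheet$sample, sheet$group)
  dip_groups <- groups[vapply(groups, function(s)
    all(sheet$ploidy[match(s, sheet$sample)] == 2L), logical(1))]
  polyploids <- sheet$sample[sheet$ploidy > 2L]

  # --- sharing --------------------------------------------------------
  if (isTRUE(stages$sharing) && length(dip_groups) >= 2 &&
      length(polyploids) >= 1) {
    results$sharing <- run_stage("sharing", {
      sm <- sharing_matrix(snvs, dip_groups, polyploids,
                           totals = params$totals %||% NULL)
      tab <- data.frame(row = rownames(sm$pct), round(sm$pct, 4),
                        check.names = FALSE)
      write.table(tab, file.path(cfg$out_dir, "sharing.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      sm
    })
    summary$sharing <- lapply(setNames(nm = polyploids), function(p)
      rank_parents(results$sharing, p))
  }

  # --- diversity ------------------------------------------------------
  if (isTRUE(stages$diversity)) {
    results$diversity <- run_stage("diversity", {
      rows <- lapply(names(dip_groups), function(g) {
        dv <- nei_gene_diversity(snvs, dip_groups[[g]],
                                 n_total_sites = genome_length)
        data.frame(group = g, H = dv$H, n_sites = dv$n_sites,
                   stringsAsFactors = FALSE)
      })
      tab <- do.call(rbind, rows)
      write.table(tab, file.path(cfg$out_dir, "diversity.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      tab
    })
    summary$diversity <- setNames(as.list(results$diversity$H),
                                  results$diversity$group)
  }

  # --- phylogeny ------------------------------------------------------
  if (isTRUE(stages$phylogeny)) {
    results$phylogeny <- run_stage("phylogeny", {
      aln <- build_pseudoalignment(snvs, cfg$reference, mode = "nuclear")
      trimmed <- trim_alignment(aln)
      tree <- bootstrap_support(trimmed,
                                n_reps = params$bootstrap %||% 100,
                                seed = derive_seed(cfg$seed, "phylogeny"))
      write_newick(tree, file.path(cfg$out_dir, "tree.nwk"))
      write_alignment(trimmed, file.path(cfg$out_dir, "alignment.fasta"),
                      "fasta")
      list(tree = tree, n_columns = ncol(trimmed$seq))
    })
    summary$phylogeny <- list(
      n_alignment_columns = results$phylogeny$n_columns,
      newick = ape::write.tree(results$phylogeny$tree))
  }

  # --- introgression --------------------------------------------------
  if (isTRUE(stages$dstat) && length(dip_groups) >= 4 &&
      !is.null(cfg$outgroup)) {
    results$dstat <- run_stage("dstat", {
      guide <- if (!is.null(results$phylogeny)) {
        group_guide_tree(results$phylogeny$tree, dip_groups)
      } else NULL
      tab <- abba_baba_all(snvs, dip_groups, outgroup = cfg$outgroup,
                           tree = guide,
                           n_blocks = params$n_blocks %||% 50)
      write.table(tab, file.path(cfg$out_dir, "trios.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      tab
    })
    summary$dstat <- results$dstat[, c("P1", "P2", "P3", "D", "Z", "p", "q")]
  }

  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}

# collapse a sample-level tree to group level by averaging cophenetic
# distances between groups, then re-running NJ
group_guide_tree <- function(tree, groups) {
  if (length(groups) < 3) return(NULL)
  d <- ape::cophenetic.phylo(tree)
  gd <- matrix(0, length(groups), length(groups),
               dimnames = list(names(groups), names(groups)))
  for (a in names(groups)) for (b in names(groups)) {
    if (a != b) gd[a, b] <- mean(d[groups[[a]], groups[[b]], drop = FALSE])
  }
  nj_tree(gd)
}

validate_run_config <- function(config) {
  need <- c("vcf", "sample_sheet", "out_dir", "seed")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop2("run config lacks required field(s): %s",
          paste(miss, collapse = ", "))
  default_stages <- list(filter = TRUE, ploidy = TRUE, sharing = TRUE,
                         diversity = TRUE, dstat = TRUE, phylogeny = TRUE)
  config$stages <- utils::modifyList(default_stages,
                                     config$stages %||% list())
  config$params <- config$params %||% list()
  for (f in c("vcf", "sample_sheet", "repeats", "genes")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop2("validation error: %s file not found: %s", f, config[[f]])
  }
  if (isTRUE(config$stages$phylogeny)) {
    if (is.null(config$reference))
      stop2("validation error: phylogeny stage enabled but no reference given")
    if (is.character(config$reference) && !file.exists(config$reference))
      stop2("validation error: reference file not found: %s",
            config$reference)
  }
  config
}
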