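#' Load and validate a pipeline run configuration
#'
#' Accepts a YAML or JSON file, or an R list. Unknown keys are rejected;
#' defaults mirror the two-condition, three-replicate study design. A seed is
#' mandatory because every simulation stage is stochastic.
#'
#' @param config Path to a YAML/JSON config, or a named list.
#' @return A validated `run_config` list.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  defaults <- list(
    seed = NULL,
    outdir = NULL,
    stages = c("simulate", "process", "matrix", "quantify", "scc", "report"),
    model = "hub",
    conditions = c("deleted", "intact"),
    n_replicates = 3L,
    reads_per_replicate = 5000L,
    enzyme = "NlaIII",
    bin_size = 1000L,
    proximity_radius = 1000L,
    wobble = 6L,
    write_fastq = FALSE,
    scc_h = 10L,
    scc_max_distance = 100000L,
    locus = list(),
    topology = list(),
    foci = list(c("R1", "Hba"), c("Mpg", "Hba"))
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop(.cfg_err(paste("unknown config keys:",
                        paste(unknown, collapse = ", "))))
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$seed))
    stop(.cfg_err("seed is required (stochastic simulate stage)"))
  if (is.null(cfg$outdir))
    stop(.cfg_err("outdir is required"))
  if (!all(cfg$stages %in% defaults$stages))
    stop(.cfg_err("invalid stage name(s)"))
  if (!cfg$model %in% c("hub", "exclusive", "independent"))
    stop(.cfg_err("model must be hub, exclusive or independent"))
  if (!all(cfg$conditions %in% c("deleted", "intact")))
    stop(.cfg_err("conditions must be a subset of deleted/intact"))
  class(cfg) <- "run_config"
  cfg
}

.cfg_err <- function(msg)
  structure(class = c("tric_config_error", "error", "condition"),
            list(message = msg, call = NULL))
.run_err <- function(msg)
  structure(class = c("tric_run_error", "error", "condition"),
            list(message = msg, call = NULL))

.build_locus <- function(cfg) {
  args <- cfg$locus
  if (!is.null(args$elements)) args$elements <- unlist(args$elements)
  if (!is.null(args$element_types))
    args$element_types <- unlist(args$element_types)
  do.call(locus_model, args)
}

.build_params <- function(cfg) {
  args <- cfg$topology
  args$model <- cfg$model
  args$reads_per_replicate <- cfg$reads_per_replicate
  args$n_replicates <- cfg$n_replicates
  args$seed <- cfg$seed
  if (!is.null(args$hub_size_dist)) args$hub_size_dist <-
    unlist(args$hub_size_dist)
  if (!is.null(args$partner_weights)) args$partner_weights <-
    unlist(args$partner_weights)
  do.call(topology_params, args)
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order: simulate (reference, digestion,
#' allele truth, concatemer reads), process (reporter extraction and
#' duplicate removal), matrix (per-replicate scaled matrices, condition
#' means, differential matrices, pairwise profiles), quantify (focus
#' statistics across replicates), scc (replicate concordance) and report.
#' A manifest with parameters and file checksums is always written. Reruns
#' with an identical config are byte-identical.
#'
#' @param config A `run_config`, list, or config file path.
#' @return Invisibly, a list of in-memory stage results and output paths.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list(config = cfg)
  manifest <- list(config = unclass(cfg))

  run_stage <- function(name, fun) {
    before <- list.files(cfg$outdir, recursive = TRUE)
    tryCatch(fun(), error = function(e) {
      after <- list.files(cfg$outdir, recursive = TRUE)
      fresh <- setdiff(after, before)
      if (length(fresh)) {
        qdir <- file.path(cfg$outdir, "quarantine")
        dir.create(qdir, showWarnings = FALSE)
        file.rename(file.path(cfg$outdir, fresh),
                    file.path(qdir, basename(fresh)))
      }
      err <- list(stage = name, message = conditionMessage(e))
      jsonlite::write_json(err, file.path(cfg$outdir, "error.json"),
                           auto_unbox = TRUE)
      stop(.run_err(sprintf("stage '%s' failed: %s", name,
                            conditionMessage(e))))
    })
  }

  locus <- .build_locus(cfg)
  params <- .build_params(cfg)
  out <- function(...) file.path(cfg$outdir, ...)

  ## -- simulate ------------------------------------------------------------
  if ("simulate" %in% cfg$stages) {
    run_stage("simulate", function() {
      reference <- random_locus_sequence(locus, seed = cfg$seed + 104729L)
      writeLines(c(paste0(">", locus$chrom), reference),
                 out("reference.fasta"))
      map <- digest_reference(reference, enzyme(cfg$enzyme),
                              chrom = locus$chrom)
      write_fragment_map(map, out("fragments.bed"))
      sim <- simulate_experiment(locus, params, map,
                                 conditions = cfg$conditions,
                                 n_replicates = cfg$n_replicates)
      write_truth_tsv(sim$truth, out("truth.tsv"))
      write_reads_tsv(sim$reads, out("reads.tsv"))
      if (isTRUE(cfg$write_fastq)) {
        fq <- render_fastq(sim$reads, map, reference,
                           enzyme = enzyme(cfg$enzyme),
                           seed = cfg$seed + 15485863L)
        write_fastq(fq, out("reads.fastq.gz"))
      }
      res$reference <<- reference
      res$map <<- map
      res$sim <<- sim
    })
  }
  if (!length(intersect(cfg$stages,
                        c("process", "matrix", "quantify", "scc", "report"))))
    return(.finish_run(cfg, res, manifest))

  if (is.null(res$map)) {
    res$map <- read_fragment_map(out("fragments.bed"))
    res$sim <- list(reads = read_reads_tsv(out("reads.tsv")))
  }
  map <- res$map
  vp <- viewpoint_from_locus(locus, map,
                             proximity_radius = cfg$proximity_radius)
  grid <- bin_grid(locus$chrom, 0L, locus$region_length, cfg$bin_size)
  groups <- expand.grid(replicate = seq_len(cfg$n_replicates),
                        condition = cfg$conditions,
                        stringsAsFactors = FALSE)

  ## -- process -------------------------------------------------------------
  if ("process" %in% cfg$stages) {
    run_stage("process", function() {
      reps <- list(); stats <- list()
      for (g in seq_len(nrow(groups))) {
        cond <- groups$condition[g]; r <- groups$replicate[g]
        sub <- res$sim$reads[res$sim$reads$condition == cond &
                               res$sim$reads$replicate == r, , drop = FALSE]
        rr <- extract_reporters(sub, vp, map)
        filt <- attr(rr, "stats")
        rr <- remove_duplicates(rr, wobble = cfg$wobble)
        filt$duplicates_collapsed <- attr(rr, "stats")$collapsed
        key <- sprintf("%s_rep%d", cond, r)
        reps[[key]] <- rr
        stats[[key]] <- filt
        write_reporters_tsv(rr, out(paste0("reporters_", key, ".tsv")))
      }
      jsonlite::write_json(stats, out("filtering_stats.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      res$reporters <<- reps
      res$filter_stats <<- stats
    })
  }

  ## -- matrix --------------------------------------------------------------
  if ("matrix" %in% cfg$stages) {
    run_stage("matrix", function() {
      meta <- list(seed = cfg$seed, model = cfg$model)
      mats <- list(); profs <- list()
      for (key in names(res$reporters)) {
        rr <- res$reporters[[key]]
        raw <- count_multiway(rr, grid, map, vp = vp)
        mats[[key]] <- normalize_matrix(raw)
        profs[[key]] <- pairwise_profile(rr, vp, map, mode = "tri_capture")
        write_matrix(mats[[key]], out(paste0("matrix_", key)), meta = meta)
        write_profile_bedgraph(profs[[key]],
                               out(paste0("profile_", key, ".bedgraph")))
      }
      means <- list()
      for (cond in cfg$conditions) {
        keys <- grep(paste0("^", cond, "_"), names(mats), value = TRUE)
        means[[cond]] <- mean_matrix(mats[keys])
        write_matrix(means[[cond]], out(paste0("matrix_mean_", cond)),
                     meta = meta)
        write_profile_bedgraph(mean_profile(profs[keys]),
                               out(paste0("profile_mean_", cond,
                                          ".bedgraph")))
      }
      if (length(cfg$conditions) == 2L) {
        d <- differential_matrix(means[[cfg$conditions[1]]],
                                 means[[cfg$conditions[2]]])
        write_matrix(d, out(paste0("matrix_diff_", cfg$conditions[1], "_vs_",
                                   cfg$conditions[2])), meta = meta)
        res$differential <<- d
      }
      res$matrices <<- mats
      res$mean_matrices <<- means
      res$profiles <<- profs
    })
  }

  ## -- quantify ------------------------------------------------------------
  if ("quantify" %in% cfg$stages && length(cfg$conditions) == 2L) {
    run_stage("quantify", function() {
      foci <- lapply(cfg$foci, function(f) {
        f <- unlist(f)
        focus_spec(paste(vp$name, f[1], f[2], sep = "-"),
                   locus$elements[[f[1]]], locus$elements[[f[2]]])
      })
      ka <- grep(paste0("^", cfg$conditions[1], "_"), names(res$matrices),
                 value = TRUE)
      kb <- grep(paste0("^", cfg$conditions[2], "_"), names(res$matrices),
                 value = TRUE)
      fq <- quantify_foci(res$matrices[ka], res$matrices[kb], foci)
      df <- as.data.frame(fq)
      df$props_a <- vapply(df$props_a, paste, character(1), collapse = ",")
      df$props_b <- vapply(df$props_b, paste, character(1), collapse = ",")
      names(df) <- sub("_a$", paste0("_", cfg$conditions[1]), names(df))
      names(df) <- sub("_b$", paste0("_", cfg$conditions[2]), names(df))
      utils::write.table(format(df, digits = 10, trim = TRUE,
                                scientific = FALSE),
                         out("foci.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      res$foci <<- fq
    })
  }

  ## -- scc -----------------------------------------------------------------
  if ("scc" %in% cfg$stages) {
    run_stage("scc", function() {
      st <- scc_table(res$matrices, h = cfg$scc_h,
                      max_distance = cfg$scc_max_distance)
      st$scc <- format(st$scc, digits = 10, trim = TRUE, scientific = FALSE)
      utils::write.table(st, out("scc.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      res$scc <<- st
    })
  }

  ## -- report --------------------------------------------------------------
  if ("report" %in% cfg$stages) {
    run_stage("report", function() {
      res$report <<- run_report(cfg$outdir)
    })
  }
  .finish_run(cfg, res, manifest)
}

.finish_run <- function(cfg, res, manifest) {
  files <- sort(setdiff(list.files(cfg$outdir, recursive = TRUE),
                        "manifest.json"))
  files <- files[!grepl("^quarantine/", files)]
  sums <- tools::md5sum(file.path(cfg$outdir, files))
  manifest$files <- stats::setNames(as.list(unname(sums)), files)
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

#' Summarize a completed pipeline run
#'
#' Tabulates, from the stage outputs alone: per-focus replicate proportions
#' with group means, SEMs, t and p; the replicate SCC table; and the
#' filtering funnel counts. Written as both JSON and a plain-text summary.
#' Regenerating the report from an unchanged run directory is
#' byte-identical.
#'
#' @param run_dir Directory produced by [run_pipeline()].
#' @return Invisibly, the report list.
#' @export
run_report <- function(run_dir) {
  need <- c("foci.tsv", "scc.tsv", "filtering_stats.json")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing))
    stop(.run_err(paste("incomplete run; missing:",
                        paste(missing, collapse = ", "))))
  foci <- utils::read.table(file.path(run_dir, "foci.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  sccs <- utils::read.table(file.path(run_dir, "scc.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  filt <- jsonlite::read_json(file.path(run_dir, "filtering_stats.json"),
                              simplifyVector = TRUE)
  report <- list(foci = foci, scc = sccs, filtering = filt)
  jsonlite::write_json(report, file.path(run_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  txt <- c("tricontact run report", "=====================", "",
           "Three-way focus quantification:")
  for (i in seq_len(nrow(foci))) {
    txt <- c(txt, sprintf(
      "  %s: %s vs %s (t = %s, df = %s, two-tailed p = %s)",
      foci$focus[i], foci[i, 2], foci[i, 3], foci$t[i], foci$df[i],
      foci$p[i]))
  }
  txt <- c(txt, "", "Replicate SCC:",
           sprintf("  %s vs %s: %s", sccs$a, sccs$b, sccs$scc), "",
           "Filtering funnel (per replicate):")
  for (key in names(filt)) {
    f <- filt[[key]]
    txt <- c(txt, sprintf(
      "  %s: %s reads in, %s no-viewpoint, %s reporterless, %s dup-collapsed, %s out",
      key, f$input_reads, f$no_viewpoint, f$reporterless_reads,
      f$duplicates_collapsed, f$surviving_reads - f$duplicates_collapsed))
  }
  writeLines(txt, file.path(run_dir, "report.txt"))
  invisible(report)
}
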