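#' Pipeline configuration
#'
#' Either point the pipeline at existing inputs (`genome`, `gff`,
#' `manifest` file paths plus `targets`/`u6` FASTA) or set
#' `simulate = TRUE` to generate the synthetic dataset first. Stage
#' parameters are the stage defaults unless overridden.
#'
#' @param simulate generate synthetic inputs with [generate_genome()].
#' @param sim a [simulation_config()] (when `simulate = TRUE`).
#' @param genome,gff,manifest,targets,u6 input file paths (when
#'   `simulate = FALSE`).
#' @param out_dir output directory for result tables (`NULL`: no files).
#' @param seed RNG seed for the run.
#' @param locus,cd,snrna,duplex stage parameter lists
#'   ([locus_params()], [cd_params()], [snrna_params()], duplex
#'   thresholds for [predict_sites()]).
#' @param de_method DE engine for [test_de()].
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = TRUE, sim = simulation_config(),
                            genome = NULL, gff = NULL, manifest = NULL,
                            targets = NULL, u6 = NULL, out_dir = NULL,
                            seed = 42L,
                            locus = locus_params(), cd = cd_params(),
                            snrna = snrna_params(),
                            duplex = list(min_pairs = NULL, max_mm = 1L,
                                          max_gu = 2L),
                            de_method = "exact") {
  structure(as.list(environment()), class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full sRNA annotation pipeline
#'
#' Executes simulate (optional) -> locus calling -> C/D snoRNA detection
#' -> methylation-target prediction -> snRNA evaluation -> differential
#' expression, and joins everything into a per-locus report. Loci passing
#' no detector are labelled `orphan`; when several detectors fire, the
#' documented precedence is snoRNA > snRNA > orphan (conflicts are noted
#' in the `conflict` column). U6 is detected first so that detected U6
#' (or the `u6` input) can serve as the pairing partner for U2/U4
#' evaluation.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` with elements `report`,
#'   `loci`, `candidates`, `sites`, `snrna_reports`, `de`, `counts`,
#'   `manifest`, and `truth` (when simulated).
#' @export
run_all <- function(config = pipeline_config()) {
  cfg <- config
  set.seed(cfg$seed)
  truth <- NULL

  if (isTRUE(cfg$simulate)) {
    sim <- .stage("simulate", {
      s <- generate_genome(cfg$sim)
      reads <- simulate_libraries(s$annotation, s$truth)
      list(annotation = s$annotation, truth = s$truth, reads = reads,
           manifest = cbind(s$truth$config$libraries,
                            reads_path = NA_character_),
           targets = s$truth$targets, u6 = s$truth$u6)
    })
    annotation <- sim$annotation; truth <- sim$truth
    reads <- sim$reads; manifest <- sim$manifest
    targets <- sim$targets; u6_seq <- sim$u6
  } else {
    inp <- .stage("read-inputs", {
      if (is.null(cfg$genome) || is.null(cfg$gff) || is.null(cfg$manifest))
        stop("genome, gff and manifest are required when simulate = FALSE")
      sequences <- read_fasta(cfg$genome)
      annotation <- read_gff3(cfg$gff, sequences)
      manifest <- read_manifest(cfg$manifest)
      reads <- lapply(manifest$reads_path, read_reads_bed)
      names(reads) <- manifest$library_id
      targets <- if (!is.null(cfg$targets)) read_fasta(cfg$targets) else NULL
      u6_seq <- if (!is.null(cfg$u6)) read_fasta(cfg$u6)[[1]] else NULL
      list(annotation = annotation, manifest = manifest, reads = reads,
           targets = targets, u6 = u6_seq)
    })
    annotation <- inp$annotation; manifest <- inp$manifest
    reads <- inp$reads; targets <- inp$targets; u6_seq <- inp$u6
  }

  loci <- .stage("call-loci", {
    cov <- build_coverage(reads, annotation)
    loci <- call_loci(cov, reads, annotation, cfg$locus)
    infer_cap_status(loci, reads, manifest, cfg$locus)
  })

  seqs <- vapply(seq_len(nrow(loci)), function(i)
    extract_sequence(annotation$sequences[[loci$chrom[i]]], loci$strand[i],
                     loci$start[i], loci$end[i]), character(1))

  candidates <- .stage("find-snorna", {
    cand <- list()
    for (i in seq_len(nrow(loci))) {
      cc <- assemble_cd_candidates(seqs[i], params = cfg$cd,
                                   locus_id = loci$locus[i])
      cand <- c(cand, cc)
    }
    cand
  })

  sites <- .stage("predict-targets", {
    if (is.null(targets) || !length(candidates)) {
      data.frame()
    } else {
      do.call(rbind, lapply(candidates, predict_sites, targets = targets,
                            params = cfg$duplex))
    }
  })

  snrna_reports <- .stage("find-snrna", {
    # pass 1: U6 (needs no partner); then use it for U2/U4
    u6_pass <- vapply(seqs, function(s)
      evaluate_snrna_candidate(s, "U6", params = cfg$snrna)$pass, logical(1))
    if (is.null(u6_seq) && any(u6_pass)) u6_seq <- seqs[which(u6_pass)[1]]
    reports <- list()
    for (i in seq_len(nrow(loci))) {
      per <- list()
      for (k in c("U1", "U2", "U4", "U5", "U6")) {
        per[[k]] <- if (k %in% c("U2", "U4") && is.null(u6_seq)) NULL
          else evaluate_snrna_candidate(seqs[i], k, u6_sequence = u6_seq,
                                        params = cfg$snrna)
      }
      reports[[loci$locus[i]]] <- per
    }
    reports
  })

  counts <- .stage("quantify", quantify(loci, reads))
  de <- .stage("diffexpr", {
    ok <- tryCatch({
      man <- manifest[!manifest$te_treated, ]
      min(table(man$condition)) >= 2 && length(unique(man$condition)) == 2
    }, error = function(e) FALSE)
    if (isTRUE(ok)) test_de(counts, manifest, method = cfg$de_method)
    else NULL
  })

  report <- .stage("report", {
    rep <- loci
    sno_ids <- vapply(candidates, `[[`, character(1), "locus_id")
    snk <- vapply(seq_len(nrow(loci)), function(i) {
      pass <- vapply(snrna_reports[[loci$locus[i]]], function(r)
        !is.null(r) && r$pass, logical(1))
      if (any(pass)) paste(names(pass)[pass], collapse = ",")
      else NA_character_
    }, character(1))
    rep$snorna <- rep$locus %in% sno_ids
    rep$snrna_kind <- snk
    rep$class <- ifelse(rep$snorna, "snoRNA",
                        ifelse(!is.na(snk), paste0("snRNA:", snk), "orphan"))
    rep$conflict <- rep$snorna & !is.na(snk)
    if (!is.null(de)) {
      rep$log2fc <- de$log2fc[match(rep$locus, de$locus)]
      rep$de_q <- de$q[match(rep$locus, de$locus)]
      rep$de_flag <- de$de_flag[match(rep$locus, de$locus)]
    }
    rep
  })

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, f) if (!is.null(df) && nrow(df))
      write.table(df, file.path(cfg$out_dir, f), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    wt(loci, "loci.tsv")
    wt(sites, "sites.tsv")
    if (!is.null(de)) wt(de, "de.tsv")
    wt(report, "report.tsv")
  }

  structure(list(report = report, loci = loci, candidates = candidates,
                 sites = sites, snrna_reports = snrna_reports, de = de,
                 counts = counts, manifest = manifest, truth = truth),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("nmsrna pipeline result:", nrow(x$loci), "loci;",
      length(x$candidates), "C/D snoRNA candidate(s);",
      if (is.null(x$sites) || !nrow(x$sites)) 0 else nrow(x$sites),
      "methylation site(s);",
      if (is.null(x$de)) 0 else sum(x$de$de_flag), "DE locus/loci\n")
  print(table(x$report$class))
  invisible(x)
}
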