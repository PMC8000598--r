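#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: the locus layout, per-strain
#' simulation parameters (or paths to existing FASTQ libraries), replicate
#' structure, analysis settings, and output location.
#'
#' @param outdir output directory (created if absent).
#' @param region_lengths lengths of the seven rDNA regions in transcription
#'   order (ETS1, 18S, ITS1, 5.8S, ITS2, 25S, ETS2).
#' @param wt_params,mut_params `strain_params` for the two strains, used
#'   when libraries are simulated.
#' @param n_reads reads per simulated library.
#' @param n_replicates replicate libraries per strain.
#' @param analysis an [analysis_config()].
#' @param seed master seed; all stage seeds derive from it.
#' @param wt_fastqs,mut_fastqs optional character vectors of existing FASTQ
#'   paths (one per replicate). When given, the simulate stage is skipped
#'   for that strain and the files are used as input.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir,
                            region_lengths = c(100L, 180L, 80L, 60L, 80L,
                                               340L, 60L),
                            wt_params = strain_params(
                              termination_prob = 5e-4,
                              duplicate_rate = 0.1,
                              offtarget_frac = 0.05),
                            mut_params = strain_params(
                              termination_prob = 2.5e-3,
                              pause_gc_weight = 1,
                              duplicate_rate = 0.1,
                              offtarget_frac = 0.05),
                            n_reads = 20000L,
                            n_replicates = 3L,
                            analysis = analysis_config(),
                            seed = 1L,
                            wt_fastqs = NULL,
                            mut_fastqs = NULL) {
  stopifnot(n_reads > 0, n_replicates >= 2)
  for (p in c(wt_fastqs, mut_fastqs))
    if (!file.exists(p))
      stop("input FASTQ not found: ", p, call. = FALSE)
  structure(list(
    outdir = outdir,
    region_lengths = as.integer(region_lengths),
    wt_params = wt_params,
    mut_params = mut_params,
    n_reads = as.integer(n_reads),
    n_replicates = as.integer(n_replicates),
    analysis = analysis,
    seed = as.integer(seed),
    wt_fastqs = wt_fastqs,
    mut_fastqs = mut_fastqs
  ), class = "pipeline_config")
}

# Deterministic per-stage seed derivation, kept within 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1009 + 97 * k) %% 2147483647)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(
    config[setdiff(names(config), "outdir")],
    auto_unbox = TRUE, force = TRUE, digits = NA)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full NET-seq analysis pipeline
#'
#' Simulate (unless FASTQ inputs are supplied) -> preprocess -> align and
#' build occupancy tracks -> strain comparison -> pause-logo analysis, with
#' every artifact written under `config$outdir` and listed, with MD5
#' checksums, in `manifest.json`. Identical configuration and seed produce
#' identical checksums. Any stage failure aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with `manifest` (data.frame of files and
#'   checksums), `tracks`, `comparison`, `pauselogo`, `locus`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  chash <- config_hash(config)
  seed <- config$seed
  files <- character()
  out <- function(...) file.path(config$outdir, paste0(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  locus <- stage("template", {
    l <- generate_template(config$region_lengths, seed = derive_seed(seed, 0))
    write_template_fasta(l, out("template.fa"))
    write_region_annotation(l, out("regions.tsv"))
    l
  })
  files <- c(out("template.fa"), out("regions.tsv"))

  strains <- list(
    wt = list(params = config$wt_params, fastqs = config$wt_fastqs),
    mut = list(params = config$mut_params, fastqs = config$mut_fastqs)
  )
  tracks <- list(wt = list(), mut = list())
  all_stats <- list()

  for (sn in names(strains)) {
    for (r in seq_len(config$n_replicates)) {
      lib <- paste0(sn, "_rep", r)
      k <- (match(sn, names(strains)) - 1L) * config$n_replicates + r
      fq <- strains[[sn]]$fastqs[r]

      raw <- stage("simulate", {
        if (is.null(strains[[sn]]$fastqs)) {
          sim <- simulate_reads(locus, strains[[sn]]$params, config$n_reads,
                                seed = derive_seed(seed, k),
                                read_prefix = paste0(lib, "_"))
          write_fastq(sim$reads, out(lib, ".fastq"))
          write_truth_tsv(sim$truth, out(lib, "_truth.tsv"), strain = sn)
          sim$reads
        } else {
          read_fastq(fq)
        }
      })
      files <- c(files,
                 if (is.null(strains[[sn]]$fastqs))
                   c(out(lib, ".fastq"), out(lib, "_truth.tsv"))
                 else fq)

      pre <- stage("preprocess", preprocess_reads(raw))
      write_fastq(pre$reads[, c("read_id", "sequence")],
                  out(lib, "_trimmed.fastq"))
      all_stats[[lib]] <- pre$stats
      files <- c(files, out(lib, "_trimmed.fastq"))

      track <- stage("occupancy",
                     occupancy_track(pre$reads, locus, strain = sn,
                                     replicate = paste0("rep", r)))
      write_track(track, out(lib, "_track.tsv"), seed = seed,
                  config_hash = chash)
      files <- c(files, out(lib, "_track.tsv"))
      tracks[[sn]][[r]] <- track
    }
  }

  jsonlite::write_json(all_stats, out("preprocess_stats.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, out("preprocess_stats.json"))

  comparison <- stage("compare", {
    cmp <- compare_strains(tracks$wt, tracks$mut, locus, config$analysis)
    write_tsv_with_header(cmp$positions, out("positions.tsv"), seed, chash)
    write_tsv_with_header(cmp$regions, out("regions_ks.tsv"), seed, chash)
    for (nm in names(cmp$smoothed))
      write_tsv_with_header(cmp$smoothed[[nm]], out("smoothed_", nm, ".tsv"),
                            seed, chash)
    cmp
  })
  files <- c(files, out("positions.tsv"), out("regions_ks.tsv"),
             vapply(names(comparison$smoothed),
                    function(nm) out("smoothed_", nm, ".tsv"), ""))

  pauselogo <- stage("pauselogo", {
    pl <- pause_logo_analysis(comparison$median_wt, comparison$median_mut,
                              locus, config$analysis)
    write_windows_fasta(pl$windows_wt, out("pause_windows_wt.fa"))
    write_windows_fasta(pl$windows_mut, out("pause_windows_mut.fa"))
    write_difflogo_tsv(pl$difflogo, out("difflogo.tsv"), seed, chash)
    pl
  })
  files <- c(files, out("pause_windows_wt.fa"), out("pause_windows_mut.fa"),
             out("difflogo.tsv"))

  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE
  )
  jsonlite::write_json(
    list(tool = "polinetseq",
         version = as.character(packageVersion("polinetseq")),
         seed = seed, config = chash, files = manifest),
    out("manifest.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(manifest = manifest, tracks = tracks,
                 comparison = comparison, pauselogo = pauselogo,
                 locus = locus))
}
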