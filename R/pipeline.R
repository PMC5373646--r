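#' Default run configuration
#'
#' All analysis parameters with their standard defaults: read filters
#' 20-40 nt and at most 2 mismatches, centre mapping, metagene
#' normalization window 70-100 nt upstream of the stop codon with the
#' 1-count and 50-nt-gap gene filters, 5-codon RPKM masking and the
#' 100-count comparison gate, RPOR eligibility of a 65-nt gap and
#' 0.1 RPM/nt density with a 20-60 nt post-ORF window and zero removal,
#' and the recoding-detector thresholds.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    paths = list(genome = NULL, annotation = NULL, reads = NULL,
                 mrna_reads = NULL, confounders = NULL),
    simulate = NULL,   # sim_params() overrides; NULL = use paths
    tracks = list(mapping = "center", min_len = 20L, max_len = 40L,
                  max_mm = 2L),
    metagene = list(window_up = 100L, window_down = 60L,
                    norm_window = c(-100L, -70L), min_window_counts = 1,
                    min_downstream_gap = 50),
    expression = list(mask_codons = 5L, min_counts = 100),
    rpor = list(min_gap = 65, min_density = 0.1, post_from = 20L,
                post_to = 60L, drop_zeros = TRUE),
    recoding = list(drop_threshold = 0.3, min_pre_density = 0.2,
                    min_region_counts = 10),
    frameshift = NULL  # list(chrom, strand, orf1 = c(a,b), orf2 = c(c,d))
  )
}

#' Read and validate a run configuration
#'
#' Reads YAML (or accepts a list), overlays it on
#' \code{\link{default_config}}, and rejects unknown keys.
#'
#' @param config Path to a YAML file, or a (possibly partial) config list.
#' @return Validated full config list.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  merge_config(default_config(), config, path = "")
}

merge_config <- function(base, override, path) {
  if (is.null(override)) return(base)
  unknown <- setdiff(names(override), names(base))
  if (length(unknown) && length(names(base))) {
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  }
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]],
                                 paste0(path, ".", nm))
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(config), f)
  unname(tools::md5sum(f))
}

write_stamped_tsv <- function(df, path, stamp) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(stamp, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full termination-analysis pipeline
#'
#' Executes the stages in dependency order: obtain genome/annotation and
#' density tracks (from the simulator when \code{config$simulate} is set,
#' otherwise from the configured input paths), then expression
#' quantification, stop-aligned metagene profiles (overall and per stop
#' codon), the RPOR table, recoding classification, and optionally the
#' two-ORF frameshift estimate. All TSV outputs carry a provenance stamp
#' (package version, seed, config MD5). Re-running with an identical
#' configuration and inputs reproduces byte-identical outputs.
#'
#' @param config A config list or YAML path (see
#'   \code{\link{read_run_config}}).
#' @param outdir Output directory for TSVs (created if needed);
#'   \code{NULL} skips writing.
#' @return (Invisibly) list with \code{orfs, tracks, expression,
#'   metagene, rpor, recoding, frameshift, config}.
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL) {
  config <- read_run_config(config)
  hash <- config_hash(config)
  seed <- config$seed

  if (!is.null(config$simulate)) {
    sp <- do.call(sim_params, config$simulate)
    sim <- simulate_genome(sp, seed = seed)
    genome <- sim$genome
    orfs <- sim$orfs
    tracks <- simulate_tracks(sim, seed = seed + 1L)
    fp <- tracks$fp; mrna <- tracks$mrna
  } else {
    p <- config$paths
    if (is.null(p$genome) || is.null(p$annotation) || is.null(p$reads)) {
      stop("config must set paths$genome, paths$annotation and paths$reads ",
           "(or a simulate block)")
    }
    for (f in c(p$genome, p$annotation, p$reads, p$mrna_reads)) {
      if (!is.null(f) && !file.exists(f)) stop("missing input: ", f)
    }
    genome <- read_genome(p$genome)
    orfs <- load_annotation(genome, p$annotation)
    read_any <- function(path) {
      if (grepl("\\.(sam|bam)$", path, ignore.case = TRUE)) {
        read_reads_sam(path)
      } else read_reads_tsv(path)
    }
    tc <- config$tracks
    fp <- normalize_per_million(build_track(
      read_any(p$reads), genome, mapping = tc$mapping,
      min_len = tc$min_len, max_len = tc$max_len, max_mm = tc$max_mm))
    mrna <- if (!is.null(p$mrna_reads)) {
      normalize_per_million(build_track(
        read_any(p$mrna_reads), genome, mapping = "coverage",
        min_len = tc$min_len, max_len = tc$max_len, max_mm = tc$max_mm))
    } else NULL
  }

  confounders <- list()
  if (!is.null(config$paths$confounders)) {
    for (f in config$paths$confounders) {
      gr <- rtracklayer::import(f, format = "bed")
      confounders[[basename(f)]] <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
        stringsAsFactors = FALSE
      )
    }
  }

  ec <- config$expression
  expression <- quantify_expression(orfs, fp, mrna,
                                    mask_codons = ec$mask_codons,
                                    min_counts = ec$min_counts)

  mc <- config$metagene
  mg_all <- metagene_profile(orfs, fp,
                             min_window_counts = mc$min_window_counts,
                             min_downstream_gap = mc$min_downstream_gap,
                             window_up = mc$window_up,
                             window_down = mc$window_down,
                             norm_window = mc$norm_window)
  strata <- stratify(orfs)
  mg_strat <- list()
  for (sc in c("UAA", "UAG", "UGA")) {
    ids <- strata[[sc]]
    if (length(ids) < 3L) next
    mg_strat[[sc]] <- tryCatch(
      metagene_profile(orfs[orfs$gene_id %in% ids, ], fp,
                       min_window_counts = mc$min_window_counts,
                       min_downstream_gap = mc$min_downstream_gap,
                       window_up = mc$window_up,
                       window_down = mc$window_down,
                       norm_window = mc$norm_window, stratum = sc),
      error = function(e) NULL)
  }

  rc <- config$rpor
  rpor_tab <- rpor_table(orfs, fp, mrna, min_gap = rc$min_gap,
                         min_density = rc$min_density,
                         post_from = rc$post_from, post_to = rc$post_to,
                         mask_codons = ec$mask_codons)

  dc <- config$recoding
  elig <- eligible_genes(orfs, fp, mrna, min_gap = rc$min_gap,
                         min_density = rc$min_density)
  recoding <- if (any(elig)) {
    classify_genes(orfs, genome, fp, eligible = elig,
                   drop_threshold = dc$drop_threshold,
                   min_pre_density = dc$min_pre_density,
                   min_region_counts = dc$min_region_counts,
                   confounders = confounders)
  } else NULL

  fs <- NULL
  if (!is.null(config$frameshift)) {
    fc <- config$frameshift
    fs <- frameshift_percent(fp, fc$chrom, fc$strand,
                             unlist(fc$orf1), unlist(fc$orf2))
  }

  result <- list(orfs = orfs, tracks = list(fp = fp, mrna = mrna),
                 expression = expression,
                 metagene = c(list(all = mg_all), mg_strat),
                 rpor = rpor_tab, recoding = recoding, frameshift = fs,
                 config = config)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    stamp <- paste0("# riboterm ",
                    as.character(utils::packageVersion("riboterm")),
                    " seed=", seed, " config_md5=", hash)
    write_stamped_tsv(as.data.frame(orfs), file.path(outdir, "orfs.tsv"), stamp)
    write_stamped_tsv(expression, file.path(outdir, "expression.tsv"), stamp)
    for (nm in names(result$metagene)) {
      write_stamped_tsv(as.data.frame(result$metagene[[nm]]),
                        file.path(outdir, paste0("metagene_", nm, ".tsv")),
                        stamp)
    }
    write_stamped_tsv(rpor_tab, file.path(outdir, "rpor.tsv"), stamp)
    if (!is.null(recoding)) {
      write_stamped_tsv(recoding, file.path(outdir, "recoding.tsv"), stamp)
    }
    if (!is.null(fs)) {
      write_stamped_tsv(data.frame(percent_frameshift = fs),
                        file.path(outdir, "frameshift.tsv"), stamp)
    }
  }
  invisible(result)
}
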