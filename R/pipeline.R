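# Orchestration: qc -> quantify -> differential -> annotation -> target
# prediction over a single declarative config, with format-validating
# readers and a run manifest (output hashes + config snapshot).

#' Assemble and validate a pipeline configuration
#'
#' @param fastq_manifest data frame with columns `sample`, `condition`,
#'   `path` (one FASTQ per replicate), or path to such a TSV.
#' @param hairpin_fasta,mature_gff3,genomic_bed,utr_fasta,contaminant_fasta
#'   reference file paths (`contaminant_fasta` and `utr_fasta` optional).
#' @param out_dir output directory for result tables.
#' @param ref_condition condition treated as the denominator (default:
#'   first in the manifest).
#' @param adapter 3' adapter sequence.
#' @param min_len,max_len read length bounds (default 18 / 34).
#' @param alpha significance level (default 0.05).
#' @param fc2,fc10 fold tiers; requires `fc10 >= fc2 > 1`.
#' @param max_gap cluster gap in bp (default 10000).
#' @param dg_max target-prediction energy threshold (default -20, < 0).
#' @param pseudo optional CPM pseudocount.
#' @param seed integer seed recorded in the manifest.
#' @return validated config list of class `mir_config`.
#' @export
pipeline_config <- function(fastq_manifest, hairpin_fasta, mature_gff3,
                            genomic_bed = NULL, utr_fasta = NULL,
                            contaminant_fasta = NULL, out_dir,
                            ref_condition = NULL,
                            adapter = TRUSEQ_SMALL_RNA_ADAPTER,
                            min_len = 18, max_len = 34, alpha = 0.05,
                            fc2 = 2, fc10 = 10, max_gap = 10000,
                            dg_max = -20, pseudo = NULL, seed = 1) {
  if (is.character(fastq_manifest) && length(fastq_manifest) == 1L) {
    fastq_manifest <- read.delim(fastq_manifest, stringsAsFactors = FALSE)
  }
  need <- c("sample", "condition", "path")
  if (!all(need %in% names(fastq_manifest))) {
    stop("configuration error: fastq_manifest needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!(fc2 > 1) || !(fc10 >= fc2)) {
    stop("configuration error: fold tiers must satisfy fc10 >= fc2 > 1",
         call. = FALSE)
  }
  if (!(dg_max < 0)) {
    stop("configuration error: dg_max must be negative", call. = FALSE)
  }
  if (!(min_len >= 1) || !(max_len >= min_len) || !(alpha > 0 && alpha < 1) ||
      !(max_gap >= 0)) {
    stop("configuration error: invalid threshold", call. = FALSE)
  }
  for (f in c("hairpin_fasta", "mature_gff3")) {
    if (!file.exists(get(f))) {
      stop("configuration error: missing input for field `", f, "`: ", get(f),
           call. = FALSE)
    }
  }
  missing_fq <- !file.exists(fastq_manifest$path)
  if (any(missing_fq)) {
    stop("configuration error: missing FASTQ: ",
         paste(fastq_manifest$path[missing_fq], collapse = ", "),
         call. = FALSE)
  }
  structure(list(
    fastq_manifest = fastq_manifest, hairpin_fasta = hairpin_fasta,
    mature_gff3 = mature_gff3, genomic_bed = genomic_bed,
    utr_fasta = utr_fasta, contaminant_fasta = contaminant_fasta,
    out_dir = out_dir, ref_condition = ref_condition, adapter = adapter,
    min_len = min_len, max_len = max_len, alpha = alpha, fc2 = fc2,
    fc10 = fc10, max_gap = max_gap, dg_max = dg_max, pseudo = pseudo,
    seed = as.integer(seed)), class = "mir_config")
}

with_stage_error <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes, in order: format validation, per-library cleaning, hairpin
#' alignment and mature counting, differential analysis, genomic
#' clustering and seed-family assignment of upregulated (mark2 = UP)
#' miRNAs, and target prediction of upregulated matures against the
#' UTRs. Each stage writes its table(s) under `out_dir`; any stage
#' failure halts with a stage-named error. Outputs are deterministic
#' given config and inputs.
#'
#' @param config a `mir_config` from [pipeline_config()].
#' @return run manifest of class `mir_manifest`: data frame of stage
#'   outputs with md5 hashes; attributes `config` (snapshot) and
#'   `results` (in-memory stage results).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "mir_config"))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  outputs <- data.frame(stage = character(0), output = character(0),
                        path = character(0), stringsAsFactors = FALSE)
  current_stage <- "validate"
  results <- list()
  emit <- function(df, name) {
    p <- file.path(config$out_dir, name)
    write_tsv_table(df, p)
    outputs[nrow(outputs) + 1L, ] <<- list(current_stage, name, p)
  }

  current_stage <- "validate"
  with_stage_error("validate", {
    paths <- c(config$fastq_manifest$path,
               config$hairpin_fasta, config$mature_gff3,
               config$genomic_bed, config$utr_fasta,
               config$contaminant_fasta)
    rep <- validate_formats(paths, hairpin_fasta = config$hairpin_fasta)
    if (any(!rep$ok)) {
      stop("invalid input file(s): ",
           paste(sprintf("%s (%s)", rep$file[!rep$ok], rep$message[!rep$ok]),
                 collapse = "; "))
    }
  })

  hairpins <- with_stage_error("load_reference", read_fasta_seqs(config$hairpin_fasta))
  matures <- with_stage_error("load_reference", {
    m <- read_mature_gff3(config$mature_gff3)
    m$sequence <- substr(hairpins[m$hairpin], m$x, m$y)
    m
  })
  contaminants <- if (!is.null(config$contaminant_fasta)) {
    with_stage_error("load_reference", read_fasta_seqs(config$contaminant_fasta))
  } else character(0)

  current_stage <- "qc"
  qc <- with_stage_error("qc", {
    res <- lapply(seq_len(nrow(config$fastq_manifest)), function(i) {
      clean_library(config$fastq_manifest$path[i], config$adapter,
                    contaminants, config$min_len, config$max_len)
    })
    names(res) <- config$fastq_manifest$sample
    emit(do.call(rbind, lapply(names(res), function(s)
      qc_report_table(res[[s]], s))), "qc_report.tsv")
    res
  })
  results$qc <- lapply(qc, function(x) x$report)

  current_stage <- "quant"
  counts <- with_stage_error("quant", {
    alns <- lapply(qc, function(x) align_reads(x$reads, hairpins))
    cm <- count_mature(alns, matures, hairpins)
    emit(data.frame(miRNA = rownames(cm$counts), cm$counts,
                    check.names = FALSE), "counts.tsv")
    emit(mapping_stats(cm), "mapping_stats.tsv")
    cm
  })
  results$counts <- counts

  current_stage <- "differential"
  de <- with_stage_error("differential", {
    groups <- config$fastq_manifest$condition
    d <- run_differential(counts, groups, ref_group = config$ref_condition,
                          alpha = config$alpha, fc2 = config$fc2,
                          fc10 = config$fc10, pseudo = config$pseudo)
    emit(d$table, "differential.tsv")
    emit(d$volcano, "volcano.tsv")
    d
  })
  results$differential <- de

  up <- de$table$miRNA[de$table$mark2 == "UP"]
  current_stage <- "annotate"
  with_stage_error("annotate", {
    up_matures <- matures[matures$name %in% up, , drop = FALSE]
    fam <- assign_families(up_matures)
    emit(as.data.frame(fam), "families.tsv")
    results$families <- fam
    if (!is.null(config$genomic_bed)) {
      loci <- read_bed6(config$genomic_bed)
      loci_up <- loci[loci$name %in% up_matures$hairpin, , drop = FALSE]
      cl <- find_clusters(loci_up, config$max_gap)
      emit(as.data.frame(cl), "clusters.tsv")
      results$clusters <- cl
    }
  })

  current_stage <- "targets"
  with_stage_error("targets", {
    if (!is.null(config$utr_fasta) && length(up)) {
      utrs <- read_fasta_seqs(config$utr_fasta)
      up_matures <- matures[matures$name %in% up, , drop = FALSE]
      pred <- predict_targets(up_matures, utrs, dg_max = config$dg_max)
      emit(as.data.frame(pred), "target_sites.tsv")
      summ <- summarize_targets(pred)
      emit(summ$per_gene, "target_summary.tsv")
      emit(summ$histogram, "target_histogram.tsv")
      results$targets <- list(sites = pred, summary = summ)
    }
  })

  manifest <- outputs
  manifest$md5 <- unname(tools::md5sum(manifest$path))
  attr(manifest, "config") <- config
  attr(manifest, "results") <- results
  class(manifest) <- c("mir_manifest", "data.frame")
  manifest
}

validate_fastq_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  if (n %% 4 != 0) {
    stop(sprintf("malformed FASTQ %s: truncated record at line %d",
                 path, (n %/% 4) * 4 + 1), call. = FALSE)
  }
  if (n == 0) return(invisible(TRUE))
  heads <- seq(1, n, by = 4)
  bad_head <- heads[!startsWith(lines[heads], "@")]
  if (length(bad_head)) {
    stop(sprintf("malformed FASTQ %s: missing '@' header at line %d",
                 path, bad_head[1]), call. = FALSE)
  }
  plus <- heads + 2L
  bad_plus <- plus[!startsWith(lines[plus], "+")]
  if (length(bad_plus)) {
    stop(sprintf("malformed FASTQ %s: missing '+' separator at line %d",
                 path, bad_plus[1]), call. = FALSE)
  }
  bad_len <- heads[nchar(lines[heads + 1L]) != nchar(lines[heads + 3L])]
  if (length(bad_len)) {
    stop(sprintf("malformed FASTQ %s: sequence/quality length mismatch at line %d",
                 path, bad_len[1] + 1L), call. = FALSE)
  }
  invisible(TRUE)
}

#' Validate input file formats
#'
#' Checks FASTQ 4-line structure (headers, separators, quality length),
#' FASTA headers, GFF3 coordinate sanity (start <= end; within the
#' hairpin when `hairpin_fasta` is given), and BED coordinate sanity.
#' Reporting only: never throws.
#'
#' @param paths character vector of file paths; format inferred from
#'   extension (`.fastq/.fq`, `.fasta/.fa`, `.gff3/.gff`, `.bed`).
#' @param hairpin_fasta optional hairpin FASTA used to cross-check GFF3
#'   mature spans against hairpin lengths.
#' @return data frame with columns `file`, `format`, `ok`,
#'   `first_bad_line`, `message`.
#' @export
validate_formats <- function(paths, hairpin_fasta = NULL) {
  paths <- paths[!vapply(paths, is.null, TRUE)]
  hp_len <- if (!is.null(hairpin_fasta) && file.exists(hairpin_fasta)) {
    nchar(read_fasta_seqs(hairpin_fasta))
  } else NULL
  rows <- lapply(paths, function(p) {
    fmt <- c(fastq = "fastq", fq = "fastq", fasta = "fasta", fa = "fasta",
             gff3 = "gff3", gff = "gff3", bed = "bed")[
               tolower(tools::file_ext(p))]
    if (is.na(fmt)) fmt <- "unknown"
    res <- list(ok = TRUE, line = NA_integer_, msg = "ok")
    err <- function(line, msg) list(ok = FALSE, line = line, msg = msg)
    if (!file.exists(p)) {
      res <- err(NA_integer_, "file not found")
    } else if (fmt == "fastq") {
      res <- tryCatch({ validate_fastq_file(p); res },
                      error = function(e) {
                        ln <- suppressWarnings(as.integer(
                          sub(".*line (\\d+).*", "\\1", conditionMessage(e))))
                        err(ln, conditionMessage(e))
                      })
    } else if (fmt == "fasta") {
      lines <- readLines(p, warn = FALSE)
      if (!length(lines) || !startsWith(lines[1], ">")) {
        res <- err(1L, "FASTA must start with a '>' header")
      } else {
        seq_lines <- which(!startsWith(lines, ">"))
        bad <- seq_lines[!grepl("^[ACGTUNacgtun]*$", lines[seq_lines])]
        if (length(bad)) res <- err(bad[1], "non-nucleotide characters")
      }
    } else if (fmt == "gff3") {
      lines <- readLines(p, warn = FALSE)
      body <- which(!startsWith(lines, "#") & nzchar(lines))
      for (i in body) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
        if (length(f) < 9) { res <- err(i, "fewer than 9 columns"); break }
        s <- suppressWarnings(as.integer(f[4]))
        e <- suppressWarnings(as.integer(f[5]))
        if (is.na(s) || is.na(e) || s < 1 || s > e) {
          res <- err(i, "invalid coordinates"); break
        }
        if (!is.null(hp_len) && f[1] %in% names(hp_len) && e > hp_len[[f[1]]]) {
          res <- err(i, sprintf("span end %d beyond hairpin length %d",
                                e, hp_len[[f[1]]])); break
        }
      }
    } else if (fmt == "bed") {
      lines <- readLines(p, warn = FALSE)
      body <- which(nzchar(lines) & !startsWith(lines, "track"))
      for (i in body) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
        if (length(f) < 3) { res <- err(i, "fewer than 3 columns"); break }
        s <- suppressWarnings(as.numeric(f[2]))
        e <- suppressWarnings(as.numeric(f[3]))
        if (is.na(s) || is.na(e) || s < 0 || s >= e) {
          res <- err(i, "invalid BED coordinates"); break
        }
      }
    }
    data.frame(file = p, format = fmt, ok = res$ok,
               first_bad_line = res$line, message = res$msg,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
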