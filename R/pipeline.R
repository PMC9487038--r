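#' Pipeline configuration
#'
#' Bundles the five input files and all tunable parameters of the
#' orthologue search. Statistical defaults follow the method: seed word
#' size 6, liftOver minMatch 0.05 and FDR level alpha 0.05. Flank and
#' merge distances are genome-scale choices: the flank default suits
#' mammalian genomes and should be scaled down for small or toy genomes;
#' merge_dist defaults to twice the flank.
#'
#' @param lncrna_bed query lncRNA annotation (BED).
#' @param query_fasta,subject_fasta genome FASTA files.
#' @param subject_annotation subject gene annotation (BED or GFF3), used
#'   for background-range construction and optional annotation.
#' @param chain UCSC chain file mapping query to subject coordinates.
#' @param outdir output directory.
#' @param min_match liftOver-style minimum mapped fraction per chain.
#' @param flank_len flank (bp) added to syntenic regions and to the query
#'   sequence before alignment.
#' @param merge_dist lifted duplications closer than this merge
#'   (default 2 * flank_len).
#' @param word_size,match_reward,mismatch_penalty,xdrop,min_score
#'   built-in aligner parameters (see [aligner_params()]).
#' @param bg_size number of shuffled background ranges per lncRNA.
#' @param alpha FDR level; HSPs with q-value < alpha are significant.
#' @param seed master seed; per-lncRNA sampling derives sub-seeds from it
#'   and the lncRNA name, so worker scheduling cannot change results.
#' @param workers parallel workers for per-lncRNA stages (fork-based;
#'   results are identical to serial execution).
#' @param annotate also annotate best orthologue calls against the subject
#'   annotation.
#' @param quiet suppress progress messages.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(lncrna_bed, query_fasta, subject_fasta,
                            subject_annotation, chain, outdir,
                            min_match = 0.05, flank_len = 50000,
                            merge_dist = NULL, word_size = 6,
                            match_reward = 1, mismatch_penalty = 2,
                            xdrop = 20, min_score = 20, bg_size = 200,
                            alpha = 0.05, seed = 1L, workers = 1L,
                            annotate = FALSE, quiet = TRUE) {
  if (is.null(merge_dist)) merge_dist <- 2 * flank_len
  structure(list(
    lncrna_bed = lncrna_bed, query_fasta = query_fasta,
    subject_fasta = subject_fasta, subject_annotation = subject_annotation,
    chain = chain, outdir = outdir,
    min_match = min_match, flank_len = as.integer(flank_len),
    merge_dist = as.integer(merge_dist),
    aligner = aligner_params(word_size, match_reward, mismatch_penalty,
                             xdrop, min_score),
    bg_size = as.integer(bg_size), alpha = alpha, seed = as.integer(seed),
    workers = as.integer(workers), annotate = isTRUE(annotate),
    quiet = isTRUE(quiet)
  ), class = "pipeline_config")
}

input_paths <- function(config) {
  c(lncrna_bed = config$lncrna_bed, query_fasta = config$query_fasta,
    subject_fasta = config$subject_fasta,
    subject_annotation = config$subject_annotation, chain = config$chain)
}

# hash of the scientific parameters + input file contents; workers and
# quiet are excluded because they must not change results
config_hash <- function(config) {
  params <- config[c("min_match", "flank_len", "merge_dist", "bg_size",
                     "alpha", "seed", "annotate")]
  params$engine_tag <- config$aligner$engine_tag
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(params, tmp, auto_unbox = TRUE, digits = NA)
  unname(paste(c(tools::md5sum(tmp), tools::md5sum(input_paths(config))),
               collapse = ""))
}

read_manifest <- function(path) {
  if (file.exists(path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else list(config_hash = "", stages = list())
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
}

plog <- function(config, ...) if (!config$quiet) message(sprintf(...))

apply_lnc <- function(config, names, f) {
  if (config$workers > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(names, f, mc.cores = config$workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(names, f)
  }
}

read_stage_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = NA, comment.char = "")
}

write_stage_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full orthologue-search pipeline
#'
#' Executes lift, synteny construction, foreground alignment, background
#' estimation, significance filtering, chaining, best-orthologue selection
#' and classification, with optional gene annotation of the calls. The
#' algorithm is atomic per lncRNA, so per-lncRNA stages run on
#' \code{config$workers} forked workers with results identical to serial
#' execution. Each stage dumps its intermediate file under
#' \code{config$outdir} and records completion in \code{manifest.json};
#' reruns with an unchanged configuration skip completed stages and reuse
#' the intermediates, so downstream parameters can be adjusted without
#' recomputing upstream stages.
#'
#' Output files: \code{bestSignificant.bed}, \code{significant.bed},
#' \code{insignificant.bed}, \code{unaligned.bed}, \code{unlifted.txt},
#' \code{summary.tsv}, \code{orthologues.json}, and (with
#' \code{annotate = TRUE}) \code{annotation.tsv}.
#'
#' @param config a [pipeline_config()].
#' @return the output directory, invisibly; the per-lncRNA summary is in
#'   \code{summary.tsv}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- input_paths(config)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing) > 0) {
    stop("missing input file(s): ",
         paste(sprintf("%s (%s)", missing, names(missing)), collapse = ", "))
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  mpath <- file.path(config$outdir, "manifest.json")
  hash <- config_hash(config)
  manifest <- read_manifest(mpath)
  if (!identical(manifest$config_hash, hash)) {
    manifest <- list(config_hash = hash, stages = list())
  }
  done <- function(stage) isTRUE(manifest$stages[[stage]])
  mark <- function(stage) {
    manifest$stages[[stage]] <<- TRUE
    write_manifest(manifest, mpath)
  }
  out <- function(f) file.path(config$outdir, f)

  query_genome <- load_genome(config$query_fasta)
  subject_genome <- load_genome(config$subject_fasta)
  subject_sizes <- genome_sizes(subject_genome)
  query_sizes <- genome_sizes(query_genome)
  lncrnas <- read_annotation(config$lncrna_bed, "bed")
  if (any(duplicated(lncrnas$name))) stop("lncRNA names must be unique")
  subj_annot <- annotation_set(read_annotation(config$subject_annotation),
                               subject_sizes)

  ## stage: lift ------------------------------------------------------
  if (done("lift")) {
    lifted_all <- read_stage_tsv(out("lifted.tsv"))
    plog(config, "lift: reused %d lifted regions", nrow(lifted_all))
  } else {
    chains <- parse_chain_file(config$chain)
    lifted_list <- lapply(seq_len(nrow(lncrnas)), function(i) {
      lift_range(lncrnas[i, , drop = FALSE], chains, config$min_match)
    })
    lifted_all <- do.call(rbind, lifted_list)
    write_stage_tsv(lifted_all, out("lifted.tsv"))
    mark("lift")
    plog(config, "lift: %d regions for %d lncRNAs", nrow(lifted_all),
         nrow(lncrnas))
  }

  ## stage: synteny ---------------------------------------------------
  if (done("synteny")) {
    syntenies <- read_stage_tsv(out("syntenies.tsv"))
  } else {
    syn_list <- lapply(lncrnas$name, function(nm) {
      l <- lifted_all[lifted_all$name == nm, , drop = FALSE]
      s <- build_syntenies(l, config$merge_dist, config$flank_len,
                           subject_sizes)
      if (nrow(s) == 0) return(NULL)
      s$name <- nm
      s$synteny_id <- sprintf("%s|%d", nm, seq_len(nrow(s)))
      s
    })
    syntenies <- do.call(rbind, syn_list)
    if (is.null(syntenies)) {
      syntenies <- cbind(granges(), data.frame(synteny_id = character()))
    }
    write_stage_tsv(syntenies, out("syntenies.tsv"))
    mark("synteny")
    plog(config, "synteny: %d regions", nrow(syntenies))
  }

  # flanked query range per lncRNA (clamped); its strand-aware sequence is
  # the query for both foreground and background alignment
  flanked_query <- function(nm) {
    lnc <- lncrnas[lncrnas$name == nm, , drop = FALSE]
    flank_ranges(lnc, config$flank_len, query_sizes)
  }

  empty_genome_hsps <- function() {
    data.frame(lncrna = character(), synteny_id = character(),
               query_chrom = character(), query_start = integer(),
               query_end = integer(), subject_chrom = character(),
               subject_start = integer(), subject_end = integer(),
               subject_strand = character(), orientation = character(),
               score = numeric(), aligned_length = integer(),
               identity = numeric(), stringsAsFactors = FALSE)
  }

  ## stage: align -----------------------------------------------------
  if (done("align")) {
    hsps_all <- read_stage_tsv(out("hsps.tsv"))
  } else {
    res <- apply_lnc(config, lncrnas$name, function(nm) {
      lnc <- lncrnas[lncrnas$name == nm, , drop = FALSE]
      syns <- syntenies[syntenies$name == nm, , drop = FALSE]
      if (nrow(syns) == 0) return(empty_genome_hsps())
      fq <- flanked_query(nm)
      qseq <- extract_sequence(query_genome, fq)
      per_syn <- lapply(seq_len(nrow(syns)), function(si) {
        syn <- syns[si, , drop = FALSE]
        sseq <- extract_sequence(subject_genome,
                                 within(syn, strand <- "+"))
        h <- find_hsps(qseq, sseq, config$aligner)
        if (nrow(h) == 0) return(NULL)
        h <- hsps_to_genome(h, fq, syn)
        h <- prune_hsps(h, lnc)
        if (nrow(h) == 0) return(NULL)
        h$lncrna <- nm
        h$synteny_id <- syn$synteny_id
        h
      })
      got <- do.call(rbind, per_syn)
      if (is.null(got)) empty_genome_hsps() else
        got[, names(empty_genome_hsps())]
    })
    hsps_all <- do.call(rbind, res)
    rownames(hsps_all) <- NULL
    write_stage_tsv(hsps_all, out("hsps.tsv"))
    mark("align")
    plog(config, "align: %d pruned HSPs", nrow(hsps_all))
  }

  ## stage: background ------------------------------------------------
  bg_dir <- out("backgrounds")
  # only lncRNAs with foreground HSPs need a null distribution
  need_bg <- unique(hsps_all$lncrna)
  if (!done("background")) {
    dir.create(bg_dir, showWarnings = FALSE)
    exclusions <- lifted_to_granges(lifted_all)
    invisible(apply_lnc(config, need_bg, function(nm) {
      fq <- flanked_query(nm)
      qseq <- extract_sequence(query_genome, fq)
      bg_ranges <- sample_shuffled_ranges(subj_annot, config$bg_size,
                                          exclusions,
                                          seed = derive_seed(config$seed, nm))
      bg <- build_background(qseq, bg_ranges, subject_genome,
                             config$aligner, lncrna_name = nm)
      write_background(bg, file.path(bg_dir, paste0(nm, ".json")))
      NULL
    }))
    mark("background")
    plog(config, "background: %d distributions of %d ranges", length(need_bg),
         config$bg_size)
  }

  ## stage: filter ----------------------------------------------------
  if (done("filter")) {
    scored_all <- read_stage_tsv(out("scored_hsps.tsv"))
  } else {
    scored_list <- lapply(need_bg, function(nm) {
      h <- hsps_all[hsps_all$lncrna == nm, , drop = FALSE]
      bg <- read_background(file.path(bg_dir, paste0(nm, ".json")))
      if (!identical(bg$engine_tag, config$aligner$engine_tag)) {
        stop("background for ", nm, " was built with a different engine (",
             bg$engine_tag, "); foreground and background scores must come ",
             "from the same engine")
      }
      h$p_value <- empirical_pvalue(h$score, bg)
      filter_significant(h, config$alpha)
    })
    scored_all <- do.call(rbind, scored_list)
    if (is.null(scored_all)) {
      scored_all <- empty_genome_hsps()
      scored_all$p_value <- numeric(0)
      scored_all$q_value <- numeric(0)
      scored_all$significant <- logical(0)
    }
    rownames(scored_all) <- NULL
    write_stage_tsv(scored_all, out("scored_hsps.tsv"))
    mark("filter")
    plog(config, "filter: %d of %d HSPs significant at alpha=%g",
         sum(scored_all$significant), nrow(scored_all), config$alpha)
  }

  ## stage: classify (chain + select + status) -------------------------
  if (!done("classify")) {
  statuses <- lapply(lncrnas$name, function(nm) {
    lifted <- lifted_all[lifted_all$name == nm, , drop = FALSE]
    all_h <- scored_all[scored_all$lncrna == nm, , drop = FALSE]
    sig <- all_h[all_h$significant, , drop = FALSE]
    chains <- list()
    if (nrow(sig) > 0) {
      syns <- syntenies[syntenies$name == nm, , drop = FALSE]
      for (sid in unique(sig$synteny_id)) {
        syn <- syns[syns$synteny_id == sid, , drop = FALSE]
        ch <- chain_hsps(sig[sig$synteny_id == sid, , drop = FALSE],
                         synteny = syn, lncrna_name = nm)
        if (!is.null(ch)) chains[[length(chains) + 1L]] <- ch
      }
    }
    classify_lncrna(lifted, all_h, chains, lncrna_name = nm)
  })
  names(statuses) <- lncrnas$name
  write_pipeline_outputs(statuses, lncrnas, config)
  mark("classify")
  tab <- table(vapply(statuses, function(s) s$status, character(1)))
  plog(config, "classify: %s",
       paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "))
  }

  ## optional annotation ----------------------------------------------
  if (config$annotate && !done("annotate")) {
    calls <- read_annotation(out("bestSignificant.bed"), "bed")
    write_annotation_hits(annotate_orthologues(calls, subj_annot),
                          out("annotation.tsv"))
    mark("annotate")
  }

  invisible(config$outdir)
}

chain_row <- function(ch) {
  data.frame(chrom = ch$span$chrom, start = ch$span$start, end = ch$span$end,
             name = ch$lncrna_name, score = round(ch$total_score),
             strand = ch$span$strand, stringsAsFactors = FALSE)
}

write_pipeline_outputs <- function(statuses, lncrnas, config) {
  out <- function(f) file.path(config$outdir, f)
  best_rows <- list(); sig_rows <- list(); insig_rows <- list()
  unal_rows <- list(); unlifted <- character(0)
  summary_rows <- list()
  sidecar <- list()
  for (nm in lncrnas$name) {
    st <- statuses[[nm]]
    srow <- data.frame(lncrna = nm, status = st$status, n_chains = 0L,
                       best_chrom = NA_character_, best_start = NA_integer_,
                       best_end = NA_integer_, best_strand = NA_character_,
                       total_hsp_length = NA_integer_,
                       total_score = NA_real_, stringsAsFactors = FALSE)
    side <- list(status = st$status)
    if (st$status == "unlifted") {
      unlifted <- c(unlifted, nm)
    } else if (st$status == "unaligned") {
      l <- st$payload$lifted
      unal_rows[[nm]] <- data.frame(chrom = l$chrom, start = l$start,
                                    end = l$end, name = nm, score = 0,
                                    strand = l$strand,
                                    stringsAsFactors = FALSE)
      side$lifted = st$payload$lifted
    } else if (st$status == "insignificant") {
      h <- st$payload$hsps
      insig_rows[[nm]] <- data.frame(chrom = h$subject_chrom,
                                     start = h$subject_start,
                                     end = h$subject_end, name = nm,
                                     score = round(h$score),
                                     strand = h$subject_strand,
                                     stringsAsFactors = FALSE)
      side$hsps = h
    } else {
      best <- st$payload$best
      best_rows[[nm]] <- chain_row(best)
      sig_rows[[nm]] <- do.call(rbind, lapply(st$payload$chains, chain_row))
      srow$n_chains <- length(st$payload$chains)
      srow$best_chrom <- best$span$chrom
      srow$best_start <- best$span$start
      srow$best_end <- best$span$end
      srow$best_strand <- best$span$strand
      srow$total_hsp_length <- best$total_hsp_length
      srow$total_score <- best$total_score
      side$best <- list(span = best$span, total_hsp_length = best$total_hsp_length,
                        total_score = best$total_score, hsps = best$hsps)
      side$chains <- lapply(st$payload$chains, function(ch)
        list(span = ch$span, total_hsp_length = ch$total_hsp_length,
             total_score = ch$total_score, hsps = ch$hsps))
    }
    summary_rows[[nm]] <- srow
    sidecar[[nm]] <- side
  }
  bed_or_empty <- function(rows, path) {
    if (length(rows) > 0) write_bed(do.call(rbind, rows), path)
    else writeLines(character(0), path)
  }
  bed_or_empty(best_rows, out("bestSignificant.bed"))
  bed_or_empty(sig_rows, out("significant.bed"))
  bed_or_empty(insig_rows, out("insignificant.bed"))
  bed_or_empty(unal_rows, out("unaligned.bed"))
  writeLines(unlifted, out("unlifted.txt"))
  write_stage_tsv(do.call(rbind, summary_rows), out("summary.tsv"))
  jsonlite::write_json(sidecar, out("orthologues.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(NULL)
}

#' Read the per-lncRNA status summary of a finished run
#' @param outdir pipeline output directory.
#' @return data frame, one row per input lncRNA.
#' @export
read_pipeline_summary <- function(outdir) {
  read_stage_tsv(file.path(outdir, "summary.tsv"))
}
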