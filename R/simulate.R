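# Synthetic-data generator: bacterial genomes with planted prophages
# (GC-shifted, direct-repeat flanked, carrying phage-gene cassettes)
# and particle-protected DNA read sets with truth alignments. Every
# pipeline stage can be exercised against known ground truth without
# any external data.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
          "S","T","W","Y","V")

# codons per amino acid under the standard (bacterial) code
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

random_dna <- function(n, gc) {
  p <- c(A = (100 - gc) / 200, C = gc / 200, G = gc / 200,
         T = (100 - gc) / 200)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Describe a prophage to plant in a simulated genome
#'
#' @param position 1-based start of the prophage interval.
#' @param length Interval length in bp.
#' @param gc Target GC percent of the interval (the host background has
#'   its own GC, so a deviation here emulates the GC signature of a
#'   genomic island).
#' @param repeat_length Length of the planted flanking direct repeat
#'   (attL/attR); 0 for none.
#' @param repeat_mismatches Substitutions introduced into the right
#'   repeat copy.
#' @param n_phage_genes Number of mutated phage-gene copies inserted as
#'   a cassette (0 for none).
#' @return A list understood by [simulation_config()].
#' @export
prophage_spec <- function(position, length, gc = 40,
                          repeat_length = 18L, repeat_mismatches = 0L,
                          n_phage_genes = 0L) {
  list(position = as.integer(position), length = as.integer(length),
       gc = gc, repeat_length = as.integer(repeat_length),
       repeat_mismatches = as.integer(repeat_mismatches),
       n_phage_genes = as.integer(n_phage_genes))
}

#' Simulation configuration
#'
#' Bundles all generator parameters. The defaults describe a
#' desk-scale model of a mitomycin-induced *Bacillus* lysate: a 500 kb
#' chromosome at the host GC of 46.2%, 100 nt single-end reads with a
#' 1% substitution error rate (well inside the 2% aberration a mapper
#' tolerates), a 5% carry-over of free host DNA, and either specific
#' packaging of one prophage locus or PBSX-like random packaging of
#' ~13 kb chromosomal fragments with an origin-proximal coverage bias.
#'
#' @param genome_length Chromosome length in bp.
#' @param background_gc Host GC percent.
#' @param prophages List of [prophage_spec()] entries (non-overlapping).
#' @param packaging_mode `"specific"` (fragments from one prophage
#'   locus) or `"random_13kb"` (fragments genome-wide).
#' @param specific_region Index into `prophages` of the packaged locus
#'   (specific mode).
#' @param fragment_mean,fragment_sd Packaged fragment length mean/sd in
#'   bp; defaults: the designated region's length (specific) or
#'   13000/1300 (random).
#' @param origin_bias Fold coverage enrichment at the origin (position
#'   1), decaying linearly along the map to 1x at the far end
#'   (emulating the multi-copy origin-proximal DNA of replicating
#'   cells).
#' @param read_length Read length in nt.
#' @param n_reads Number of reads to simulate.
#' @param error_rate Per-base substitution probability (<= 0.02).
#' @param background_dna_fraction Fraction of reads drawn uniformly
#'   from the whole chromosome (nuclease-surviving free host DNA).
#' @param seed Integer seed; every generator output is deterministic in
#'   `(config, seed)`.
#' @param phage_db Optional phage protein database data frame used for
#'   gene cassettes; generated with [simulate_phage_db()] when `NULL`
#'   and any prophage requests genes.
#' @return A `pp_sim_config` list.
#' @export
simulation_config <- function(genome_length = 500000L,
                              background_gc = 46.2,
                              prophages = list(prophage_spec(230000L, 40000L)),
                              packaging_mode = c("specific", "random_13kb"),
                              specific_region = 1L,
                              fragment_mean = NULL, fragment_sd = NULL,
                              origin_bias = 2,
                              read_length = 100L, n_reads = 50000L,
                              error_rate = 0.01,
                              background_dna_fraction = 0.05,
                              seed = 1L, phage_db = NULL) {
  packaging_mode <- match.arg(packaging_mode)
  if (error_rate < 0 || error_rate > 0.02) {
    stop("error_rate must be in [0, 0.02]")
  }
  if (background_dna_fraction < 0 || background_dna_fraction > 1) {
    stop("background_dna_fraction must be in [0, 1]")
  }
  pr <- prophages
  if (length(pr)) {
    st <- vapply(pr, `[[`, integer(1), "position")
    en <- st + vapply(pr, `[[`, integer(1), "length") - 1L
    o <- order(st)
    st <- st[o]; en <- en[o]
    if (any(en > genome_length)) stop("prophage interval exceeds genome")
    if (length(st) > 1L && any(st[-1L] <= en[-length(en)])) {
      stop("prophage intervals overlap")
    }
  }
  structure(
    list(genome_length = as.integer(genome_length),
         background_gc = background_gc, prophages = prophages,
         packaging_mode = packaging_mode,
         specific_region = as.integer(specific_region),
         fragment_mean = fragment_mean, fragment_sd = fragment_sd,
         origin_bias = origin_bias, read_length = as.integer(read_length),
         n_reads = as.integer(n_reads), error_rate = error_rate,
         background_dna_fraction = background_dna_fraction,
         seed = as.integer(seed), phage_db = phage_db),
    class = "pp_sim_config")
}

#' Generate a synthetic phage protein database
#'
#' Random proteins grouped into phages with family labels from the
#' standard phage taxonomy vocabulary; used both as search database and
#' as the gene pool for planted cassettes.
#'
#' @param n_phages Number of phages.
#' @param genes_per_phage Proteins per phage.
#' @param mean_len Mean protein length in aa (uniform
#'   `0.5x .. 1.5x mean_len`).
#' @param seed Integer seed.
#' @return Data frame with columns `id`, `phage`, `family`, `seq`.
#' @export
simulate_phage_db <- function(n_phages = 3L, genes_per_phage = 20L,
                              mean_len = 200L, seed = 1L) {
  families <- c("Siphoviridae", "Myoviridae", "Podoviridae")
  with_seed(seed, {
    rows <- list()
    for (p in seq_len(n_phages)) {
      phage <- sprintf("phage%02d", p)
      family <- families[(p - 1L) %% length(families) + 1L]
      for (g in seq_len(genes_per_phage)) {
        len <- sample(seq(round(0.5 * mean_len), round(1.5 * mean_len)), 1L)
        seq <- paste(c("M", sample(AA20, len - 1L, replace = TRUE)),
                     collapse = "")
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("%s_g%03d", phage, g), phage = phage,
          family = family, seq = seq, stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    rownames(df) <- NULL
    df
  })
}

# Point-mutate a protein (substitutions only, M start kept).
mutate_protein <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1L]]
  hit <- which(stats::runif(length(ch)) < rate)
  hit <- hit[hit > 1L]
  for (i in hit) ch[i] <- sample(setdiff(AA20, ch[i]), 1L)
  paste(ch, collapse = "")
}

# Back-translate a protein, choosing synonymous codons weighted toward
# a target GC so cassettes do not erase the region's GC signature.
back_translate <- function(protein, gc_target, codons = codon_table()) {
  base_w <- c(A = (100 - gc_target) / 200, C = gc_target / 200,
              G = gc_target / 200, T = (100 - gc_target) / 200)
  ch <- strsplit(protein, "")[[1L]]
  out <- character(length(ch))
  for (i in seq_along(ch)) {
    cands <- codons[[ch[i]]]
    w <- vapply(cands, function(cd) {
      prod(base_w[strsplit(cd, "")[[1L]]])
    }, numeric(1))
    out[i] <- if (length(cands) == 1L) cands else
      sample(cands, 1L, prob = w)
  }
  out[1L] <- "ATG"
  paste0(paste(out, collapse = ""), sample(c("TAA", "TAG", "TGA"), 1L))
}

#' Simulate a genome with planted prophages
#'
#' Builds an i.i.d. background sequence at the configured host GC,
#' resamples each prophage interval at its own GC, plants a direct
#' repeat at the interval boundaries (the right copy carrying the
#' configured number of substitutions), and inserts a cassette of
#' mutated, back-translated phage genes from the phage protein
#' database. Deterministic in `(config, seed)`.
#'
#' @param config A [simulation_config()].
#' @return A `pp_sim_truth` list: `genome` (a circular [pp_genome()]),
#'   `regions` (region data frame with GC/repeat/gene metadata),
#'   `phage_db` (the database used for cassettes), `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "pp_sim_config"))
  need_db <- any(vapply(config$prophages, `[[`, integer(1),
                        "n_phage_genes") > 0L)
  db <- config$phage_db
  if (is.null(db) && need_db) {
    db <- simulate_phage_db(seed = config$seed)
  }
  truth <- with_seed(config$seed, {
    seq <- strsplit(random_dna(config$genome_length, config$background_gc),
                    "")[[1L]]
    codons <- codon_table()
    regs <- list()
    for (k in seq_along(config$prophages)) {
      pp <- config$prophages[[k]]
      s <- pp$position; e <- pp$position + pp$length - 1L
      body <- strsplit(random_dna(pp$length, pp$gc), "")[[1L]]
      # flanking direct repeat: left copy at the region start, right
      # copy (with mismatches) at the region end
      if (pp$repeat_length > 0L) {
        rep_seq <- strsplit(random_dna(pp$repeat_length, pp$gc), "")[[1L]]
        body[seq_len(pp$repeat_length)] <- rep_seq
        right <- rep_seq
        if (pp$repeat_mismatches > 0L) {
          at <- sample(pp$repeat_length, pp$repeat_mismatches)
          for (i in at) right[i] <- sample(setdiff(c("A","C","G","T"),
                                                   right[i]), 1L)
        }
        body[(pp$length - pp$repeat_length + 1L):pp$length] <- right
      }
      genes <- character(0)
      cass_start <- NA_integer_; cass_end <- NA_integer_
      if (pp$n_phage_genes > 0L) {
        phage <- sample(unique(db$phage), 1L)
        pool <- db$seq[db$phage == phage]
        take <- sample(pool, min(pp$n_phage_genes, length(pool)))
        offset <- pp$repeat_length + 100L
        cass_start <- s + offset - 1L
        for (g in take) {
          nt <- back_translate(mutate_protein(g, 0.05), pp$gc, codons)
          if (offset + nchar(nt) > pp$length - pp$repeat_length - 100L) break
          body[offset + seq_len(nchar(nt)) - 1L] <- strsplit(nt, "")[[1L]]
          genes <- c(genes, g)
          cass_end <- s + offset + nchar(nt) - 2L
          offset <- offset + nchar(nt) + sample(50:200, 1L)
        }
        if (length(genes) == 0L) cass_start <- NA_integer_
      }
      seq[s:e] <- body
      regs[[k]] <- data.frame(
        label = sprintf("sim_Pp%d", k), start = s, end = e, gc = pp$gc,
        repeat_length = pp$repeat_length,
        repeat_mismatches = pp$repeat_mismatches,
        n_genes_planted = length(genes),
        cassette_start = cass_start, cassette_end = cass_end,
        stringsAsFactors = FALSE)
    }
    genome <- pp_genome("sim_genome", paste(seq, collapse = ""),
                        circular = TRUE)
    list(genome = genome,
         regions = if (length(regs)) do.call(rbind, regs) else
           regions_df(character(0), integer(0), integer(0)))
  })
  structure(list(genome = truth$genome, regions = truth$regions,
                 phage_db = db, config = config),
            class = "pp_sim_truth")
}

#' @export
print.pp_sim_truth <- function(x, ...) {
  cat(sprintf("<pp_sim_truth> %s bp genome, %d planted prophage region(s), mode %s\n",
              format(x$genome$length, big.mark = ","), nrow(x$regions),
              x$config$packaging_mode))
  invisible(x)
}

#' Simulate particle-protected DNA reads with truth alignments
#'
#' Packaged fragments are drawn either uniformly from the designated
#' prophage locus (specific mode; fragment length defaults to the
#' region length, i.e. headful packaging of the phage's own genome) or
#' genome-wide with a linear origin-proximity bias (random mode; mean
#' 13 kb, the PBSX packaging unit). One read of `read_length` nt is
#' sampled per fragment, uniformly within it, on a random strand, with
#' i.i.d. substitution errors at `error_rate`. A
#' `background_dna_fraction` of reads is drawn uniformly from the whole
#' chromosome in either mode. Deterministic in `(config, seed)`.
#'
#' @param truth A `pp_sim_truth` from [simulate_genome()].
#' @param fastq,sam Optional output paths; written when non-`NULL`.
#' @return A `pp_sim_reads` list: `origins` (data frame `read_id`,
#'   `start`, `end`, `strand`, `source`), `reads` (reference-oriented
#'   sequences), `fastq`, `sam`, `n_reads`.
#' @export
simulate_particle_reads <- function(truth, fastq = NULL, sam = NULL) {
  stopifnot(inherits(truth, "pp_sim_truth"))
  config <- truth$config
  if (config$n_reads <= 0L) stop("n_reads must be positive")
  L <- truth$genome$length
  rl <- config$read_length
  res <- with_seed(config$seed + 1L, {
    n_bg <- round(config$n_reads * config$background_dna_fraction)
    n_fr <- config$n_reads - n_bg

    if (config$packaging_mode == "specific") {
      if (nrow(truth$regions) == 0L) {
        stop("specific packaging requires at least one prophage region")
      }
      reg <- truth$regions[config$specific_region, ]
      reg_len <- reg$end - reg$start + 1L
      fmean <- if (is.null(config$fragment_mean)) reg_len else config$fragment_mean
      fsd <- if (is.null(config$fragment_sd)) round(0.02 * fmean) else config$fragment_sd
      flen <- pmax(rl, pmin(reg_len,
                            round(stats::rnorm(n_fr, fmean, fsd))))
      fstart <- reg$start +
        floor(stats::runif(n_fr) * (reg_len - flen + 1))
    } else {
      fmean <- if (is.null(config$fragment_mean)) 13000L else config$fragment_mean
      fsd <- if (is.null(config$fragment_sd)) 1300L else config$fragment_sd
      flen <- pmax(rl, round(stats::rnorm(n_fr, fmean, fsd)))
      # linear origin-proximity bias: weight B at the origin (position
      # 1) decaying to 1 at the far end of the map
      d <- (seq_len(L) - 1L) / (L - 1L)
      w <- config$origin_bias - (config$origin_bias - 1) * d
      cdf <- cumsum(w)
      fstart <- findInterval(stats::runif(n_fr) * cdf[L], cdf) + 1L
    }
    rstart_fr <- fstart + floor(stats::runif(n_fr) * (flen - rl + 1))
    if (config$packaging_mode == "random_13kb") {
      # fragments wrap around the circular chromosome; reads stay
      # linear, so the rare read crossing the origin is pinned inside
      rstart_fr <- (rstart_fr - 1L) %% L + 1L
      rstart_fr <- pmin(rstart_fr, L - rl + 1L)
    }
    rstart_bg <- if (n_bg > 0L)
      floor(stats::runif(n_bg) * (L - rl + 1)) + 1L else integer(0)
    rstart <- c(rstart_fr, rstart_bg)
    source <- c(rep("fragment", n_fr), rep("background", n_bg))
    n <- length(rstart)
    strand <- sample(c("+", "-"), n, replace = TRUE)

    seqs <- substring(as.character(truth$genome$seq), rstart,
                      rstart + rl - 1L)
    # substitution errors, vectorized over the base matrix
    chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE),
                           use.names = FALSE), ncol = rl, byrow = TRUE)
    err <- which(stats::runif(length(chars)) < config$error_rate)
    if (length(err)) {
      alt <- rbind(c("C","G","T"), c("A","G","T"),
                   c("A","C","T"), c("A","C","G"))
      row <- match(chars[err], c("A", "C", "G", "T"))
      chars[err] <- alt[cbind(row, sample.int(3L, length(err),
                                              replace = TRUE))]
    }
    seqs <- do.call(paste0, as.data.frame(chars, stringsAsFactors = FALSE))

    list(origins = data.frame(
      read_id = sprintf("read_%06d", seq_len(n)), start = rstart,
      end = rstart + rl - 1L, strand = strand, source = source,
      stringsAsFactors = FALSE), reads = seqs)
  })

  if (!is.null(sam)) {
    qual <- strrep("I", rl)
    flag <- ifelse(res$origins$strand == "+", 0L, 16L)
    lines <- c(
      "@HD\tVN:1.6\tSO:unknown",
      sprintf("@SQ\tSN:%s\tLN:%d", truth$genome$id, L),
      "@PG\tID:prophactr\tPN:prophactr",
      sprintf("%s\t%d\t%s\t%d\t42\t%dM\t*\t0\t0\t%s\t%s",
              res$origins$read_id, flag, truth$genome$id,
              res$origins$start, rl, res$reads, qual))
    writeLines(lines, sam)
  }
  if (!is.null(fastq)) {
    out <- res$reads
    minus <- res$origins$strand == "-"
    if (any(minus)) {
      out[minus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(out[minus])))
    }
    writeLines(rbind(paste0("@", res$origins$read_id), out,
                     "+", strrep("I", rl)), fastq)
  }
  structure(list(origins = res$origins, reads = res$reads,
                 fastq = fastq, sam = sam, n_reads = nrow(res$origins)),
            class = "pp_sim_reads")
}

#' @export
print.pp_sim_reads <- function(x, ...) {
  cat(sprintf("<pp_sim_reads> %s reads (%s from fragments, %s background)\n",
              format(x$n_reads, big.mark = ","),
              format(sum(x$origins$source == "fragment"), big.mark = ","),
              format(sum(x$origins$source == "background"), big.mark = ",")))
  invisible(x)
}

#' Write a simulated genome and its truth tables to disk
#'
#' @param truth A `pp_sim_truth`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths (`fasta`, `regions`, `config`).
#' @export
write_sim_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "pp_sim_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "genome.fasta")
  set <- Biostrings::DNAStringSet(as.character(truth$genome$seq))
  names(set) <- truth$genome$id
  Biostrings::writeXStringSet(set, fasta)
  regions <- file.path(dir, "truth_regions.tsv")
  write_regions(truth$regions, regions)
  cfgp <- file.path(dir, "config.json")
  cfg <- unclass(truth$config)
  cfg$phage_db <- NULL
  cfg$prophages <- lapply(cfg$prophages, unclass)
  jsonlite::write_json(cfg, cfgp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  list(fasta = fasta, regions = regions, config = cfgp)
}
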