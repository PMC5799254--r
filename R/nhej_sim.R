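# Synthetic-data generator: NHEJ editing outcomes at a cut site, binary drug
# selection in an essential gene, and read simulation for guide cassettes and
# amplicons. Every simulator is deterministic for a fixed seed and returns a
# truth table for downstream tests.

#' NHEJ outcome model
#'
#' A transduced cell acquires a mutation with probability `p_edit`; the
#' outcome type is deletion / insertion / substitution with probabilities
#' `p_del` / `p_ins` / `p_sub` (remainder: precise repair, no scar). Indel
#' lengths follow truncated geometric laws; lesions start uniformly in the
#' `position_window` bases upstream of the cut, matching the observed
#' localization of mutations within 17 bp upstream of the SpCas9 cleavage
#' site, and deletion ends are clipped at `cut + max_ins` so every lesion
#' footprint stays inside `[cut - position_window, cut + max_ins)`.
#'
#' @param p_edit Probability a cell acquires any mutation.
#' @param p_del,p_ins,p_sub Outcome-type probabilities (sum <= 1).
#' @param del_mean,max_del Mean / truncation of the geometric deletion-length
#'   law (default mean 4, max 17).
#' @param ins_mean,max_ins Same for insertions (default mean 2, max 10).
#' @param position_window Bases upstream of the cut where lesions start.
#' @return List of class `nhej_model`.
#' @export
nhej_model <- function(p_edit = 0.8, p_del = 0.55, p_ins = 0.25,
                       p_sub = 0.10, del_mean = 4, max_del = 17L,
                       ins_mean = 2, max_ins = 10L, position_window = 17L) {
  stopifnot(p_edit >= 0, p_edit <= 1, p_del >= 0, p_ins >= 0, p_sub >= 0,
            p_del + p_ins + p_sub <= 1, max_del >= 1, max_ins >= 1,
            position_window >= 1)
  structure(list(p_edit = p_edit, p_del = p_del, p_ins = p_ins, p_sub = p_sub,
                 del_mean = del_mean, max_del = as.integer(max_del),
                 ins_mean = ins_mean, max_ins = as.integer(max_ins),
                 position_window = as.integer(position_window)),
            class = "nhej_model")
}

#' Drug-selection model for an essential hotspot gene
#'
#' An allele survives drug selection iff it is an in-frame protein change
#' altering at least one hotspot codon. In an essential gene, frameshift
#' (and nonsense) alleles are lethal, but a cell may escape with probability
#' `diploid_escape` -- haploid lines spontaneously turning diploid retain a
#' wild-type copy. Wild-type, silent and non-hotspot in-frame alleles die
#' under drug.
#'
#' @param hotspot_codons Integer protein positions whose alteration confers
#'   resistance.
#' @param essential Is the gene essential (frameshift lethal)?
#' @param diploid_escape Probability a frameshift cell survives anyway.
#' @return List of class `selection_model`.
#' @export
selection_model <- function(hotspot_codons, essential = TRUE,
                            diploid_escape = 0.02) {
  stopifnot(diploid_escape >= 0, diploid_escape <= 1)
  structure(list(hotspot_codons = as.integer(hotspot_codons),
                 essential = essential, diploid_escape = diploid_escape),
            class = "selection_model")
}

#' Simulate NHEJ editing outcomes at a cut site
#'
#' Each cell independently draws precise repair or a deletion / insertion /
#' substitution per the model. Deletions start uniformly in
#' `[cut - position_window, cut)` with truncated-geometric length (clipped at
#' `cut + max_ins`); insertions of random sequence occur at the cut;
#' substitutions fall in the upstream window.
#'
#' @param amplicon An [amplicon_reference]; lesions must fit inside it.
#' @param model An [nhej_model].
#' @param n_cells Number of cells.
#' @param seed RNG seed.
#' @param cut_coord Cut coordinate; defaults to the amplicon's.
#' @return `data.frame` of class `edit_population`: `cell`, `outcome`,
#'   `allele` (canonical op key, `""` = unedited/precise) plus a list column
#'   `ops`.
#' @export
simulate_editing <- function(amplicon, model, n_cells, seed = 1L,
                             cut_coord = amplicon$cut_coord) {
  set.seed(seed)
  pw <- model$position_window
  if (cut_coord - pw < amplicon$offset ||
      cut_coord + model$max_ins > amplicon$offset + amplicon$length)
    stop("lesion window extends outside the amplicon")
  edited <- runif(n_cells) < model$p_edit
  outcome <- rep("unedited", n_cells)
  u <- runif(n_cells)
  pd <- model$p_del; pi2 <- model$p_ins; ps <- model$p_sub
  outcome[edited & u < pd] <- "del"
  outcome[edited & u >= pd & u < pd + pi2] <- "ins"
  outcome[edited & u >= pd + pi2 & u < pd + pi2 + ps] <- "sub"
  outcome[edited & u >= pd + pi2 + ps] <- "precise"
  refc <- strsplit(amplicon$sequence, "")[[1]]
  ops <- vector("list", n_cells)
  for (i in seq_len(n_cells)) ops[[i]] <- list()
  idel <- which(outcome == "del")
  if (length(idel)) {
    start <- cut_coord - sample.int(pw, length(idel), replace = TRUE)
    len <- pmin(rgeom(length(idel), 1 / model$del_mean) + 1L, model$max_del)
    end <- pmin(start + len, cut_coord + model$max_ins)
    for (k in seq_along(idel))
      ops[[idel[k]]] <- list(op_del(start[k], end[k] - start[k]))
  }
  iins <- which(outcome == "ins")
  if (length(iins)) {
    len <- pmin(rgeom(length(iins), 1 / model$ins_mean) + 1L, model$max_ins)
    for (k in seq_along(iins)) {
      seq <- paste(sample(c("A", "C", "G", "T"), len[k], replace = TRUE),
                   collapse = "")
      ops[[iins[k]]] <- list(op_ins(cut_coord, seq))
    }
  }
  isub <- which(outcome == "sub")
  if (length(isub)) {
    pos <- cut_coord - sample.int(pw, length(isub), replace = TRUE)
    for (k in seq_along(isub)) {
      ref <- refc[pos[k] - amplicon$offset + 1L]
      ops[[isub[k]]] <- list(op_sub(pos[k],
                                    sample(setdiff(c("A", "C", "G", "T"), ref), 1L)))
    }
  }
  out <- data.frame(cell = seq_len(n_cells), outcome = outcome,
                    allele = vapply(ops, op_key, ""))
  out$ops <- ops
  class(out) <- c("edit_population", "data.frame")
  attr(out, "amplicon") <- amplicon
  out
}

#' Apply binary drug selection to an edited population
#'
#' Each cell's allele is classified with [classify_and_name()]; survivors
#' follow the [selection_model()] rule. Classification is cached per distinct
#' allele so large populations stay cheap.
#'
#' @param population An `edit_population`.
#' @param selection A [selection_model].
#' @param amplicon An [amplicon_reference] with `codon_map`; defaults to the
#'   population's.
#' @param seed RNG seed for the diploid-escape draws.
#' @return The surviving subset of `population`, with `klass` and `resistant`
#'   columns added.
#' @export
simulate_selection <- function(population, selection,
                               amplicon = attr(population, "amplicon"),
                               seed = 1L) {
  set.seed(seed)
  keys <- unique(population$allele)
  vars <- lapply(keys, classify_and_name, amplicon = amplicon)
  klass <- vapply(vars, `[[`, "", "klass")
  hot <- vapply(vars, function(v)
    length(intersect(v$affected_codons, selection$hotspot_codons)) > 0 &&
      v$klass %in% c("inframe_deletion", "inframe_insertion",
                     "inframe_delins", "missense"), TRUE)
  idx <- match(population$allele, keys)   # "" (wild type) is a valid key
  k <- klass[idx]
  resistant <- hot[idx]
  lethal <- selection$essential & k %in% c("frameshift", "nonsense")
  escape <- runif(nrow(population)) < selection$diploid_escape
  survive <- resistant | (lethal & escape)
  out <- population[survive, , drop = FALSE]
  out$klass <- k[survive]
  out$resistant <- resistant[survive]
  attr(out, "amplicon") <- attr(population, "amplicon")
  class(out) <- class(population)
  out
}

#' Simulate paired-end amplicon sequencing of an allele population
#'
#' Reads are sampled multinomially by cell frequency; mate 1 is the first
#' `read_len` bases of the cell's mutant amplicon and mate 2 the reverse
#' complement of its last `read_len` bases, so the mates come from opposite
#' ends. Per-base substitution errors at `seq_error`; uniform quality.
#'
#' @param population An `edit_population` (surviving or not).
#' @param amplicon An [amplicon_reference].
#' @param depth Number of read pairs.
#' @param read_len Read length; must let both mates span the haplotype window.
#' @param seq_error Per-base substitution error rate.
#' @param seed RNG seed.
#' @param fastq1,fastq2 Optional output FASTQ paths; when `NULL` the reads are
#'   only returned.
#' @param window [window_spec()] used for the span check.
#' @return List with `reads1`, `reads2` (character), the output paths, and
#'   `truth` (`data.frame` of allele key, true frequency, sampled pairs).
#' @export
simulate_amplicon_reads <- function(population, amplicon, depth = 5000L,
                                    read_len = 150L, seq_error = 0.001,
                                    seed = 1L, fastq1 = NULL, fastq2 = NULL,
                                    window = window_spec()) {
  set.seed(seed)
  keys <- population$allele
  tab <- table(keys)
  uniq <- names(tab)
  p <- as.numeric(tab) / length(keys)
  mut <- vapply(uniq, function(k)
    apply_ops(amplicon$sequence, parse_op_key(k), amplicon$offset), "")
  # mate 1 covers [0, read_len) and mate 2 [L - read_len, L) of the mutant;
  # the pair spans the window when their joint coverage is contiguous (the
  # haplotype caller accepts jointly spanning mates)
  for (k in seq_along(uniq)) {
    L <- nchar(mut[k])
    if (L > 2L * read_len)
      stop("read_len too short for both mates to span the haplotype window")
  }
  draw <- sample.int(length(uniq), depth, replace = TRUE, prob = p)
  r1 <- substr(mut[draw], 1L, read_len)
  full_len <- nchar(mut[draw])
  r2 <- revcomp(substring(mut[draw], full_len - read_len + 1L, full_len))
  r1 <- add_seq_errors(r1, seq_error)
  r2 <- add_seq_errors(r2, seq_error)
  truth <- data.frame(allele = uniq, true_freq = p,
                      pairs = as.integer(tabulate(draw, length(uniq))))
  ids <- sprintf("@sim_%d", seq_len(depth))
  if (!is.null(fastq1)) write_fastq(ids, r1, fastq1)
  if (!is.null(fastq2)) write_fastq(ids, r2, fastq2)
  list(reads1 = r1, reads2 = r2, fastq1 = fastq1, fastq2 = fastq2,
       truth = truth)
}

# apply an op list to a sequence (0-based global coords -> local via offset)
apply_ops <- function(sequence, ops, offset = 0L) {
  if (!length(ops)) return(sequence)
  chars <- strsplit(sequence, "")[[1]]
  keep <- rep(TRUE, length(chars))
  repl <- chars
  ins_before <- vector("list", length(chars) + 1L)
  for (o in ops) {
    loc <- o$start - offset
    if (o$type == "del") {
      keep[(loc + 1L):(loc + o$len)] <- FALSE
    } else if (o$type == "sub") {
      repl[loc + 1L] <- o$base
    } else {
      ins_before[[loc + 1L]] <- c(ins_before[[loc + 1L]], o$seq)
    }
  }
  pieces <- character(0)
  for (i in seq_along(chars)) {
    if (!is.null(ins_before[[i]])) pieces <- c(pieces, ins_before[[i]])
    if (keep[i]) pieces <- c(pieces, repl[i])
  }
  if (!is.null(ins_before[[length(chars) + 1L]]))
    pieces <- c(pieces, ins_before[[length(chars) + 1L]])
  paste(pieces, collapse = "")
}

add_seq_errors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  n <- length(reads)
  lens <- nchar(reads)
  nerr <- rbinom(n, lens, rate)
  idx <- which(nerr > 0)
  for (i in idx) {
    pos <- sample.int(lens[i], nerr[i])
    ch <- strsplit(reads[i], "")[[1]]
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

write_fastq <- function(ids, reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0(ids, "\n", reads, "\n+\n",
                    strrep("I", nchar(reads))), con)
  invisible(path)
}

#' Pooled-screen simulation configuration
#'
#' @param library Guide `data.frame` with `guide_id`, `protospacer` and a
#'   logical `hotspot` column flagging guides whose cut lies close enough to
#'   a hotspot codon to generate resistance alleles.
#' @param n_cells Cells subjected to transduction.
#' @param moi Poisson mean of lentiviral integrations per cell (published
#'   screens used 0.25 for SpCas9 and 0.35 for AsCpf1).
#' @param depth_before,depth_after Reads per pool.
#' @param seq_error Per-base substitution error rate of the cassette reads.
#' @param flank5,flank3 Constant cassette sequences around the protospacer.
#' @param seed RNG seed.
#' @return List of class `screen_sim_config`.
#' @export
screen_sim_config <- function(library, n_cells = 20000L, moi = 0.25,
                              depth_before = 100000L, depth_after = 100000L,
                              seq_error = 0.001,
                              flank5 = "TTGTGGAAAGGACGAAACACCG",
                              flank3 = "GTTTTAGAGCTAGAAATAGCAAG",
                              seed = 1L) {
  stopifnot(moi > 0, depth_before > 0, depth_after > 0,
            !is.null(library$hotspot))
  structure(list(library = library, n_cells = as.integer(n_cells), moi = moi,
                 depth_before = as.integer(depth_before),
                 depth_after = as.integer(depth_after),
                 seq_error = seq_error, flank5 = flank5, flank3 = flank3,
                 seed = as.integer(seed)),
            class = "screen_sim_config")
}

#' Expected multi-transduction fraction under Poisson MOI
#'
#' Among transduced (>= 1 integration) cells, the fraction carrying >= 2
#' guides is `(1 - e^-m - m e^-m) / (1 - e^-m)`; about 0.165 at MOI 0.35.
#'
#' @param moi Poisson mean.
#' @return Fraction in `[0, 1)`.
#' @export
moi_multi_fraction <- function(moi) {
  (1 - exp(-moi) - moi * exp(-moi)) / (1 - exp(-moi))
}

#' Simulate a pooled mutagenesis-scanning screen
#'
#' Per-cell integration counts are Poisson(`moi`); cells with zero guides are
#' dropped (puromycin). Editing outcomes per integrated guide are drawn from
#' the NHEJ model *categorically* (type and indel length, not sequence):
#' a hotspot-capable guide yields a resistance allele when the outcome is an
#' in-frame indel or a substitution; any frameshift-length indel at the
#' essential target is lethal unless the diploid-escape coin passes. A cell
#' survives drug when it carries at least one resistance allele and no
#' unescaped lethal allele. Guide-cassette reads for the before (post
#' puromycin) and after (post drug) pools are emitted at the configured
#' depths; guides hitchhiking in multi-transduced surviving cells are emitted
#' at full weight, reproducing the double-transduction false-positive
#' mechanism.
#'
#' @param config A [screen_sim_config].
#' @param nhej An [nhej_model].
#' @param selection A [selection_model] (only `essential` and
#'   `diploid_escape` are used at this categorical level).
#' @return List with `reads_before`, `reads_after` (character vectors; also
#'   written to `fastq_before` / `fastq_after` when given) and `truth`
#'   (assignments with survival flags and expected pool fractions).
#' @param fastq_before,fastq_after Optional output FASTQ paths.
#' @export
simulate_screen <- function(config, nhej, selection,
                            fastq_before = NULL, fastq_after = NULL) {
  set.seed(config$seed)
  lib <- config$library
  k <- rpois(config$n_cells, config$moi)
  cells <- which(k > 0)
  if (!length(cells)) stop("no transduced cells; increase n_cells or moi")
  cell_of <- rep(cells, k[cells])
  guide_of <- sample.int(nrow(lib), length(cell_of), replace = TRUE)
  n_int <- length(cell_of)

  edited <- runif(n_int) < nhej$p_edit
  u <- runif(n_int)
  type <- rep("none", n_int)
  type[edited & u < nhej$p_del] <- "del"
  type[edited & u >= nhej$p_del & u < nhej$p_del + nhej$p_ins] <- "ins"
  type[edited & u >= nhej$p_del + nhej$p_ins &
         u < nhej$p_del + nhej$p_ins + nhej$p_sub] <- "sub"
  len <- integer(n_int)
  len[type == "del"] <- pmin(rgeom(sum(type == "del"), 1 / nhej$del_mean) + 1L,
                             nhej$max_del)
  len[type == "ins"] <- pmin(rgeom(sum(type == "ins"), 1 / nhej$ins_mean) + 1L,
                             nhej$max_ins)
  inframe <- (type %in% c("del", "ins") & len %% 3L == 0L) | type == "sub"
  frameshift <- type %in% c("del", "ins") & len %% 3L != 0L
  hot <- lib$hotspot[guide_of]
  resistant <- hot & type != "none" & inframe
  lethal <- selection$essential & frameshift &
    !(runif(n_int) < selection$diploid_escape)

  cell_resistant <- tapply(resistant, cell_of, any)
  cell_dead <- tapply(lethal, cell_of, any)
  surviving_cells <- as.integer(names(cell_resistant))[cell_resistant & !cell_dead]

  emit_pool <- function(gidx, depth) {
    if (!length(gidx)) return(list(reads = character(0), frac = rep(0, nrow(lib))))
    frac <- tabulate(gidx, nrow(lib)) / length(gidx)
    draw <- gidx[sample.int(length(gidx), depth, replace = TRUE)]
    reads <- paste0(config$flank5, lib$protospacer[draw], config$flank3)
    list(reads = add_seq_errors(reads, config$seq_error), frac = frac)
  }
  before <- emit_pool(guide_of, config$depth_before)
  after_idx <- guide_of[cell_of %in% surviving_cells]
  if (!length(after_idx))
    warning("zero surviving cells: after-pool is empty")
  after <- emit_pool(after_idx, config$depth_after)
  if (!is.null(fastq_before))
    write_fastq(sprintf("@before_%d", seq_along(before$reads)),
                before$reads, fastq_before)
  if (!is.null(fastq_after) && length(after$reads))
    write_fastq(sprintf("@after_%d", seq_along(after$reads)),
                after$reads, fastq_after)
  truth <- list(
    assignments = data.frame(cell = cell_of,
                             guide_id = lib$guide_id[guide_of],
                             type = type, inframe = inframe,
                             resistant = resistant, lethal = lethal,
                             survived = cell_of %in% surviving_cells),
    expected_before = setNames(before$frac, lib$guide_id),
    expected_after = setNames(after$frac, lib$guide_id),
    n_transduced = length(cells),
    n_multi = sum(k[cells] >= 2),
    surviving_cells = surviving_cells)
  list(reads_before = before$reads, reads_after = after$reads,
       fastq_before = fastq_before, fastq_after = fastq_after, truth = truth)
}
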