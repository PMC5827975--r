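# Readers and writers for the pipeline's on-disk formats: aligned FASTA,
# the two-column date table, Newick trees, minimal PDB coordinate files with
# a binding-site list, TSV result tables and the YAML run configuration.

#' Read an aligned FASTA file
#'
#' Validates on read: all sequences equal length, unique ids, residues
#' restricted to the 20 amino-acid letters plus `-` (lowercase is accepted
#' and uppercased). Errors name the offending record.
#'
#' @param path FASTA file.
#' @return character matrix alignment (rows = sequences).
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  ids <- names(ss)
  if (anyDuplicated(ids))
    stop_invalid("duplicate sequence id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(unique(nchar(seqs))) != 1L) {
    n <- nchar(seqs)
    bad <- ids[n != n[1]][1]
    stop_invalid("ragged alignment; first offending record: ", bad)
  }
  ok <- !grepl(sprintf("[^%s-]", paste(AA20, collapse = "")), seqs)
  if (!all(ok))
    stop_invalid("illegal characters in record(s): ",
                 paste(ids[!ok], collapse = ", "))
  as_msa(stats::setNames(seqs, ids))
}

#' Write an aligned FASTA file
#'
#' @param msa alignment (any form accepted by the package).
#' @param path output file.
#' @export
write_alignment <- function(msa, path) {
  s <- msa_strings(msa)
  Biostrings::writeXStringSet(Biostrings::BStringSet(s), path, width = 80L)
  invisible(path)
}

#' Read a publication-date table
#'
#' Two-column tab-separated file `seq_id TAB year` (no header). Years must
#' be integral and ids unique.
#'
#' @param path TSV file.
#' @return named integer vector of years.
#' @export
read_dates <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("seq_id", "year"),
                          colClasses = c("character", "character"))
  if (anyDuplicated(df$seq_id))
    stop_invalid("duplicate id(s) in date table: ",
                 paste(unique(df$seq_id[duplicated(df$seq_id)]), collapse = ", "))
  yr <- suppressWarnings(as.numeric(df$year))
  if (anyNA(yr) || any(yr != round(yr)))
    stop_invalid("non-integer year for id(s): ",
                 paste(df$seq_id[is.na(yr) | yr != round(yr)], collapse = ", "))
  stats::setNames(as.integer(yr), df$seq_id)
}

#' @rdname read_dates
#' @param dates named integer vector of years.
#' @export
write_dates <- function(dates, path) {
  utils::write.table(data.frame(names(dates), unname(dates)), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Join an alignment with its date table into a family
#'
#' Sequences without a date are dropped with a warning and counted in the
#' `n_undated` attribute.
#'
#' @param msa alignment.
#' @param dates named year vector from [read_dates()].
#' @return family data frame (`seq_id`, `residues`, `year`), date-ordered.
#' @export
family_from_alignment <- function(msa, dates) {
  s <- msa_strings(msa)
  have <- names(s) %in% names(dates)
  if (!all(have)) {
    warning(sum(!have), " sequence(s) without a publication date were dropped")
  }
  fam <- data.frame(seq_id = names(s)[have], residues = unname(s[have]),
                    year = unname(dates[names(s)[have]]),
                    stringsAsFactors = FALSE)
  fam <- fam[order(fam$year, fam$seq_id), , drop = FALSE]
  rownames(fam) <- NULL
  attr(fam, "n_undated") <- sum(!have)
  fam
}

#' Write a structure model as a minimal PDB plus binding-site list
#'
#' One representative atom (CA) per residue; the companion file
#' `<path>.binding` lists the 1-based indices of binding residues.
#'
#' @param structure a `structure_model`.
#' @param path output PDB file.
#' @export
write_structure <- function(structure, path) {
  n <- nrow(structure$coords)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(structure$coords)),
                   resno = seq_len(n), resid = rep("ALA", n),
                   elety = rep("CA", n), chain = rep("A", n))
  writeLines(as.character(which(structure$binding)), paste0(path, ".binding"))
  invisible(path)
}

#' Read a structure model from a minimal PDB and binding-site list
#'
#' @param path PDB file written by [write_structure()] (or any PDB with one
#'   CA per residue); `binding_path` defaults to `<path>.binding`.
#' @param binding_path file of 1-based binding residue indices.
#' @return a `structure_model` with an identity column map.
#' @export
read_structure <- function(path, binding_path = paste0(path, ".binding")) {
  pdb <- bio3d::read.pdb(path)
  ca <- pdb$atom[pdb$atom$elety == "CA", , drop = FALSE]
  coords <- as.matrix(ca[, c("x", "y", "z")])
  dimnames(coords) <- NULL
  n <- nrow(coords)
  binding <- rep(FALSE, n)
  if (file.exists(binding_path)) {
    idx <- as.integer(readLines(binding_path))
    if (anyNA(idx) || any(idx < 1L | idx > n))
      stop_invalid("invalid binding residue indices in ", binding_path)
    binding[idx] <- TRUE
  }
  structure(list(coords = coords, binding = binding,
                 column_map = seq_len(n), pocket_radius = NA_real_),
            class = "structure_model")
}

#' Write a simulated dataset to a directory
#'
#' Per family: `<id>.fasta` (aligned), `<id>.dates.tsv`, `<id>.pdb` (+
#' `.binding`), and `<id>.truth.tsv` (column site classes). Snapshot FASTA
#' files are not written here; see [write_snapshots()].
#'
#' @param dataset an `sdp_dataset`.
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (fid in names(dataset$families)) {
    fam <- dataset$families[[fid]]
    write_alignment(stats::setNames(fam$residues, fam$seq_id),
                    file.path(dir, paste0(fid, ".fasta")))
    write_dates(stats::setNames(fam$year, fam$seq_id),
                file.path(dir, paste0(fid, ".dates.tsv")))
    write_structure(dataset$structures[[fid]], file.path(dir, paste0(fid, ".pdb")))
    tr <- dataset$truth[[fid]]
    utils::write.table(
      data.frame(column = seq_along(tr$site_class_of),
                 site_class = unname(tr$site_class_of)),
      file.path(dir, paste0(fid, ".truth.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return an `sdp_dataset`-shaped list (`families`, `structures`; truth is
#'   reloaded as site-class vectors when present).
#' @export
read_dataset <- function(dir) {
  fas <- sort(list.files(dir, pattern = "\\.fasta$", full.names = TRUE))
  if (!length(fas)) stop_invalid("no .fasta files in ", dir)
  ids <- sub("\\.fasta$", "", basename(fas))
  families <- list(); structures <- list(); truth <- list()
  for (i in seq_along(ids)) {
    fid <- ids[i]
    msa <- read_alignment(fas[i])
    dates <- read_dates(file.path(dir, paste0(fid, ".dates.tsv")))
    families[[fid]] <- family_from_alignment(msa, dates)
    pdb <- file.path(dir, paste0(fid, ".pdb"))
    structures[[fid]] <- if (file.exists(pdb)) read_structure(pdb) else NULL
    tf <- file.path(dir, paste0(fid, ".truth.tsv"))
    if (file.exists(tf)) {
      tt <- utils::read.delim(tf)
      truth[[fid]] <- list(site_class_of = stats::setNames(tt$site_class, tt$column))
    }
  }
  structure(list(families = families, structures = structures, truth = truth),
            class = "sdp_dataset")
}

#' Write per-year snapshot alignments
#'
#' One FASTA per workable year, named `<family>_<year>.fasta`.
#'
#' @param family family data frame.
#' @param family_id identifier used in file names.
#' @param dir output directory.
#' @param config a [benchmark_config()].
#' @export
write_snapshots <- function(family, family_id, dir, config = benchmark_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (y in config$years) {
    snap <- remove_redundancy(snapshot_at(family, y, family_id),
                              config$redundancy_identity)
    if (snap$n_after_redundancy == 0L) next
    write_alignment(stats::setNames(snap$members$residues, snap$members$seq_id),
                    file.path(dir, sprintf("%s_%d.fasta", family_id, y)))
  }
  invisible(dir)
}

#' Write benchmark results as TSV tables
#'
#' Emits `records.tsv` (the master table; columns are 1-based where they
#' refer to alignment positions), `coverage.tsv`, `redundancy.tsv`,
#' `subfamilies.tsv`, and the per-figure summary tables from
#' [summary.sdp_benchmark()].
#'
#' @param bench an `sdp_benchmark`.
#' @param dir output directory.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(bench$records, "records.tsv")
  wt(bench$coverage, "coverage.tsv")
  wt(bench$redundancy, "redundancy.tsv")
  wt(bench$subfamilies, "subfamilies.tsv")
  s <- summary(bench)
  wt(s$sequences_rel, "sequences_relative.tsv")
  wt(s$counts_rel, "selected_counts_relative.tsv")
  wt(s$sdp_counts_rel, "sdp_counts_relative.tsv")
  wt(s$subfamilies_rel, "subfamilies_relative.tsv")
  wt(s$distance, "relative_distance_by_year.tsv")
  invisible(dir)
}

#' Read a YAML run configuration
#'
#' Recognized keys mirror the arguments of [benchmark_config()] and
#' [simulate_benchmark_data()]; unknown keys error.
#'
#' @param path YAML file.
#' @return list with `config` (a [benchmark_config()]) and `synthetic`
#'   (generator arguments).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: ", path)
  raw <- yaml::read_yaml(path)
  cfg_keys <- names(formals(benchmark_config))
  syn_keys <- names(formals(simulate_benchmark_data))
  unknown <- setdiff(names(raw), c(cfg_keys, syn_keys, "outdir", "mode"))
  if (length(unknown))
    stop_invalid("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- do.call(benchmark_config, raw[intersect(names(raw), cfg_keys)])
  syn <- raw[intersect(names(raw), syn_keys)]
  list(config = cfg, synthetic = syn,
       outdir = raw$outdir, mode = raw$mode %||% "synthetic")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
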