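#' Read molecular structures from SDF or SMILES
#'
#' Structures are normalized through Open Babel (hydrogens made explicit,
#' formal charges written to the atom block) and parsed with ChemmineR.
#' Heavy-atom order of the source is preserved, added hydrogens are appended
#' after the heavy atoms, so atom indices reported by the package match the
#' normalized 1-based SDF numbering (identical to the input numbering for
#' SDF files that already carry explicit hydrogens; SMILES atoms are
#' numbered in their order of appearance in the string).
#'
#' Unparseable records are skipped with a warning and counted in the
#' `n_skipped` attribute of the result.
#'
#' @param path path to the input file.
#' @param format `"sdf"` or `"smiles"`.  SMILES files hold one molecule per
#'   line, optionally followed by whitespace and an identifier.
#' @return list of [mmrs_mol] objects, with attribute `n_skipped`.
#' @export
read_structures <- function(path, format = c("sdf", "smiles")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  if (!length(txt) || all(!nzchar(trimws(txt))))
    stop("empty structure file: ", path)
  if (format == "smiles") {
    lines <- txt[nzchar(trimws(txt))]
    parts <- strsplit(trimws(lines), "[ \t]+")
    smiles <- vapply(parts, `[[`, "", 1L)
    ids <- vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) > 1L) parts[[i]][[2L]] else sprintf("mol%03d", i)
    }, "")
    mols <- parse_smiles_set(smiles, ids)
  } else {
    # normalize through Open Babel so hydrogens are explicit; heavy-atom
    # order is preserved and added H are appended
    sdf_txt <- tryCatch(ob_convert("SDF", paste(txt, collapse = "\n")),
                        error = function(e) paste(txt, collapse = "\n"))
    if (!grepl("V2000", sdf_txt)) sdf_txt <- paste(txt, collapse = "\n")
    mols <- parse_sdf_text(sdf_txt)
  }
  keep <- !vapply(mols, is.null, TRUE)
  n_skipped <- sum(!keep)
  if (n_skipped)
    warning(n_skipped, " record(s) could not be parsed and were skipped")
  mols <- mols[keep]
  if (!length(mols)) stop("no parseable records in ", path)
  attr(mols, "n_skipped") <- n_skipped
  mols
}

#' Parse SMILES strings into molecule records
#'
#' @param smiles character vector of SMILES.
#' @param ids identifiers (defaults to mol001, ...).
#' @return list of [mmrs_mol] (NULL entries for unparseable input are
#'   dropped, with a warning).
#' @export
parse_smiles_set <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("mol%03d", seq_along(smiles))
  # fast path: one batch conversion; record<->id alignment is checked and
  # falls back to per-record conversion when any record fails
  batch <- tryCatch(
    ob_convert("SMI", paste0(paste(paste(smiles, ids, sep = "\t"),
                                   collapse = "\n"), "\n")),
    error = function(e) NULL)
  if (!is.null(batch) && grepl("V2000", batch)) {
    recs <- parse_sdf_text(batch)
    if (length(recs) == length(smiles) &&
        !any(vapply(recs, is.null, TRUE))) {
      for (i in seq_along(recs)) recs[[i]]$mol_id <- ids[i]
      return(recs)
    }
  }
  out <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    sdf_txt <- tryCatch(
      ob_convert("SMI", paste0(smiles[i], "\n")),
      error = function(e) NULL)
    if (is.null(sdf_txt) || !grepl("V2000", sdf_txt)) next
    rec <- parse_sdf_text(sdf_txt)
    if (length(rec) == 1L && !is.null(rec[[1L]])) {
      rec[[1L]]$mol_id <- ids[i]
      out[[i]] <- rec[[1L]]
    }
  }
  failed <- vapply(out, is.null, TRUE)
  if (any(failed))
    warning("unparseable SMILES skipped: ", paste(ids[failed], collapse = ", "))
  out[!failed]
}

ob_convert <- function(from, source) {
  txt <- suppressWarnings(ChemmineOB::convertFormat(
    from, "SDF", source = source,
    options = data.frame(names = "h", args = "")))
  txt
}

# Parse (possibly multi-record) V2000 SDF text into mmrs_mol objects.
# Normalization through Open Babel guarantees explicit H and atom-block
# charge codes; ChemmineR does the block parsing.
parse_sdf_text <- function(txt) {
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(txt, tf)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(tf))
  ids <- ChemmineR::sdfid(sdfset)
  lapply(seq_along(sdfset), function(i) {
    tryCatch({
      sdf <- sdfset[[i]]
      ab <- ChemmineR::atomblock(sdf)
      bb <- ChemmineR::bondblock(sdf)
      elements <- sub("_.*$", "", rownames(ab))
      charges <- mdl_charge_code(ab[, "C6"])
      bonds <- data.frame(a = as.integer(bb[, 1]),
                          b = as.integer(bb[, 2]),
                          order = as.integer(bb[, 3]))
      id <- ids[i]
      if (is.na(id) || !nzchar(id)) id <- sprintf("mol%03d", i)
      mmrs_mol(id, elements, charges, bonds)
    }, error = function(e) NULL)
  })
}

# MDL atom-block charge field: 0 none, 1..3 = +3..+1, 5..7 = -1..-3
mdl_charge_code <- function(code) {
  code <- as.integer(code)
  ch <- integer(length(code))
  pos <- code %in% 1:3; ch[pos] <- 4L - code[pos]
  neg <- code %in% 5:7; ch[neg] <- 4L - code[neg]
  ch
}

#' Filter molecules by permitted elements
#'
#' Only C, H, O, N, S, P, F, Cl, Br and I are permitted; molecules carrying
#' any other element (e.g. the boron of bortezomib) are removed.  Salts are
#' stripped to their largest organic fragment before the check.
#'
#' @param mols list of [mmrs_mol].
#' @return list with components `kept` (list of molecules) and `removed`
#'   (data.frame: mol_id, element).
#' @export
filter_elements <- function(mols) {
  removed <- data.frame(mol_id = character(0), element = character(0),
                        stringsAsFactors = FALSE)
  kept <- list()
  for (mol in mols) {
    mol <- largest_fragment(mol)
    bad <- setdiff(unique(mol$atoms$element), PERMITTED_ELEMENTS)
    if (length(bad)) {
      removed <- rbind(removed, data.frame(mol_id = mol$mol_id,
                                           element = bad[1]))
    } else {
      kept[[length(kept) + 1L]] <- mol
    }
  }
  list(kept = kept, removed = removed)
}

ENZYMES <- c("CYP3A4", "CYP2D6", "CYP2C9")
REACTION_TYPES <- c("I", "II", "III", "IV")

normalize_enzyme <- function(x) {
  y <- toupper(trimws(x))
  y <- ifelse(grepl("^CYP", y), y, paste0("CYP", y))
  y
}

#' Read site-of-metabolism annotations
#'
#' Tab-separated file with columns `mol_id`, `atom_a`, `atom_b`, `enzyme`,
#' `reaction_type`.  `atom_a`/`atom_b` are 1-based atom indices of the
#' annotated bond in the molecule's (normalized) numbering.  For C-H sites
#' (types I/II) `atom_b` may be 0, meaning "any hydrogen of atom_a"; the
#' representative hydrogen is resolved during labeling.  Duplicate rows are
#' collapsed.
#'
#' @param path path to the TSV file.
#' @return data.frame of annotations.
#' @export
read_som_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("mol_id", "atom_a", "atom_b", "enzyme", "reaction_type")
  if (!all(need %in% names(df)))
    stop("annotation file must have columns: ", paste(need, collapse = ", "))
  df$enzyme <- normalize_enzyme(df$enzyme)
  bad_e <- which(!(df$enzyme %in% ENZYMES))
  if (length(bad_e))
    stop("unknown enzyme '", df$enzyme[bad_e[1]], "' in annotation row ",
         bad_e[1])
  df$reaction_type <- toupper(trimws(df$reaction_type))
  bad_r <- which(!(df$reaction_type %in% REACTION_TYPES))
  if (length(bad_r))
    stop("unknown reaction_type '", df$reaction_type[bad_r[1]],
         "' in annotation row ", bad_r[1])
  df$atom_a <- as.integer(df$atom_a); df$atom_b <- as.integer(df$atom_b)
  ndup <- sum(duplicated(df[need]))
  if (ndup) message(ndup, " duplicated annotation row(s) collapsed")
  df <- df[!duplicated(df[need]), need, drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a substrate registry (which enzymes act on which molecule)
#'
#' TSV with columns `mol_id`, `enzyme`.  When no registry is available the
#' enzymes per molecule default to those seen in the annotation file.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns mol_id, enzyme.
#' @export
read_enzyme_registry <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("mol_id", "enzyme") %in% names(df)))
    stop("registry must have columns mol_id, enzyme")
  df$enzyme <- normalize_enzyme(df$enzyme)
  bad <- which(!(df$enzyme %in% ENZYMES))
  if (length(bad)) stop("unknown enzyme '", df$enzyme[bad[1]], "' in registry")
  unique(df[c("mol_id", "enzyme")])
}

#' Write / read an MMRS descriptor table
#'
#' The CSV carries the MMRS key columns (mol_id, atom_a, atom_b, enzyme,
#' reaction_type, symmetry_class, label) followed by the 56 descriptor
#' columns under their canonical labels (`qtot_A` ... `boord`) and the three
#' enzyme indicator columns.  A write -> read round trip reproduces the
#' table exactly.
#'
#' @param records data.frame of MMRS records (see [extract_mmrs]).
#' @param vectors numeric matrix of descriptors, one row per record.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_mmrs_table <- function(records, vectors, path) {
  if (nrow(records) != nrow(vectors))
    stop("records and descriptor matrix differ in length")
  stopifnot(identical(colnames(vectors), mmrs_feature_names()))
  out <- cbind(records[c("mol_id", "atom_a", "atom_b", "enzyme",
                         "reaction_type", "symmetry_class", "label")],
               as.data.frame(vectors, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mmrs_table
#' @export
read_mmrs_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  keys <- c("mol_id", "atom_a", "atom_b", "enzyme", "reaction_type",
            "symmetry_class", "label")
  feats <- mmrs_feature_names()
  if (!all(c(keys, feats) %in% names(df)))
    stop("not an MMRS table: ", path)
  list(records = df[keys], vectors = as.matrix(df[feats]))
}

#' Save / load a fitted model bundle
#'
#' A bundle is a directory holding `manifest.json` (reaction type,
#' classifier, feature-selection method, ordered feature subset,
#' hyperparameters, training seed, package version) next to the serialized
#' estimator (`estimator.rds`).
#'
#' @param bundle fitted bundle from [fit_final].
#' @param dir directory to create.
#' @return `dir` (save) or the bundle (load).
#' @export
save_model_bundle <- function(bundle, dir) {
  if (is.null(bundle$model)) stop("bundle is not fitted")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- bundle$manifest
  manifest$package_version <- as.character(utils::packageVersion("mmrsom"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  saveRDS(bundle$model, file.path(dir, "estimator.rds"))
  invisible(dir)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  ef <- file.path(dir, "estimator.rds")
  if (!file.exists(mf) || !file.exists(ef))
    stop("not a model bundle directory: ", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  cur <- as.character(utils::packageVersion("mmrsom"))
  if (!identical(manifest$package_version, cur))
    stop("bundle was written by mmrsom ", manifest$package_version,
         ", this is ", cur)
  model <- tryCatch(readRDS(ef), error = function(e)
    stop("corrupt estimator file in ", dir))
  structure(list(manifest = manifest, model = model), class = "mmrs_bundle")
}
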