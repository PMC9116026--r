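#' Construct a Cohort from data frames
#'
#' @param subjects data.frame with columns subject_id, stratum, status,
#'   age, design and either a `carried` list column or a semicolon-separated
#'   `carried` character column.
#' @param variants data.frame with at least gene, variant_id, consequence,
#'   frequency; score/annotation columns are filled with NA when absent.
#' @param metadata optional list.
#' @return A validated [Cohort-class] object.
#' @export
Cohort <- function(subjects, variants, metadata = list()) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  subjects <- as.data.frame(subjects, stringsAsFactors = FALSE)
  for (col in setdiff(VARIANT_COLS, names(variants))) {
    variants[[col]] <- switch(col,
      splice_excluded = FALSE,
      cadd = , helix = , bayesdel = , revel = , align_gvgd = NA_real_,
      domain = "none",
      NA_character_)
  }
  variants <- variants[, VARIANT_COLS]
  for (col in c("frequency", "cadd", "helix", "bayesdel", "revel",
                "align_gvgd"))
    variants[[col]] <- as.numeric(variants[[col]])
  for (col in c("gene", "variant_id", "consequence", "domain", "sge_class",
                "hdr_class", "clinvar_class"))
    variants[[col]] <- as.character(variants[[col]])
  variants$splice_excluded <- as.logical(variants$splice_excluded)
  if (!is.list(subjects$carried))
    subjects$carried <- parseCarried(subjects$carried)
  subjects <- subjects[, SUBJECT_COLS]
  subjects$age <- suppressWarnings(as.numeric(subjects$age))
  new("Cohort", subjects = subjects, variants = variants, metadata = metadata)
}

parseCarried <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  lapply(strsplit(x, ";", fixed = TRUE),
         function(v) v[nzchar(trimws(v))])
}

formatCarried <- function(lst) {
  vapply(lst, function(v) paste(v, collapse = ";"), character(1L))
}

#' Read a cohort from variants.tsv and subjects.tsv
#'
#' Both files are tab-separated with mandatory header rows. Missing values
#' are encoded as the token "NA". The subjects file stores carried variant
#' ids as a semicolon-separated list (empty allowed). Referential integrity
#' (unique ids, carried ids resolving in the catalog) is verified and
#' violations raise an error naming the offending row.
#'
#' @param variantsPath,subjectsPath file paths.
#' @return A [Cohort-class].
#' @export
readCohort <- function(variantsPath, subjectsPath) {
  for (p in c(variantsPath, subjectsPath))
    if (!file.exists(p)) stopf("file not found: %s", p)
  v <- read.delim(variantsPath, sep = "\t", stringsAsFactors = FALSE,
                  na.strings = "NA", quote = "", check.names = TRUE)
  s <- read.delim(subjectsPath, sep = "\t", stringsAsFactors = FALSE,
                  na.strings = "NA", quote = "", check.names = TRUE,
                  colClasses = c(carried = "character"))
  need_v <- c("gene", "variant_id", "consequence", "frequency")
  if (!all(need_v %in% names(v)))
    stopf("variants file missing columns: %s",
          paste(setdiff(need_v, names(v)), collapse = ", "))
  need_s <- c("subject_id", "stratum", "status", "age", "design", "carried")
  if (!all(need_s %in% names(s)))
    stopf("subjects file missing columns: %s",
          paste(setdiff(need_s, names(s)), collapse = ", "))
  if (!is.numeric(v$frequency)) {
    bad <- which(is.na(suppressWarnings(as.numeric(v$frequency))) &
                 !is.na(v$frequency))
    stopf("unparseable frequency at variants line %d",
          if (length(bad)) bad[1L] + 1L else NA_integer_)
  }
  if (anyDuplicated(v$variant_id)) {
    i <- which(duplicated(v$variant_id))[1L]
    stopf("duplicate variant_id '%s' at variants line %d", v$variant_id[i], i + 1L)
  }
  if (anyDuplicated(s$subject_id)) {
    i <- which(duplicated(s$subject_id))[1L]
    stopf("duplicate subject_id '%s' at subjects line %d", s$subject_id[i], i + 1L)
  }
  carried <- parseCarried(s$carried)
  unknown <- !vapply(carried, function(ids) all(ids %in% v$variant_id), logical(1L))
  if (any(unknown)) {
    i <- which(unknown)[1L]
    miss <- setdiff(carried[[i]], v$variant_id)[1L]
    stopf("subject '%s' (subjects line %d) carries unknown variant '%s'",
          s$subject_id[i], i + 1L, miss)
  }
  s$carried <- carried
  if (is.logical(v$splice_excluded %||% NA)) {
  } else if (!is.null(v$splice_excluded)) {
    v$splice_excluded <- as.logical(v$splice_excluded)
  }
  Cohort(subjects = s, variants = v)
}

#' Write a cohort to variants.tsv / subjects.tsv
#'
#' Inverse of [readCohort()]; round-trips all fields (missing values as the
#' "NA" token, carried ids joined with ";").
#'
#' @param cohort a Cohort.
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vPath <- file.path(dir, "variants.tsv")
  sPath <- file.path(dir, "subjects.tsv")
  write.table(variants(cohort), vPath, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  s <- subjects(cohort)
  s$carried <- formatCarried(s$carried)
  write.table(s, sPath, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(c(variants = vPath, subjects = sPath))
}

#' Stratified training/validation split
#'
#' A fraction of population-design subjects from the eligible strata is
#' sampled into the validation set; everyone else (including all
#' familial-design subjects) stays in training. Sampling is stratified by
#' (stratum, status) so that validation case-control proportions track the
#' eligible pool, and is deterministic for a fixed seed.
#'
#' @param cohort a Cohort.
#' @param fraction sampling fraction in (0, 1).
#' @param eligibleStrata character vector of stratum labels eligible for
#'   validation sampling.
#' @param seed integer seed.
#' @return list(training = Cohort, validation = Cohort).
#' @export
splitTrainValidation <- function(cohort, fraction, eligibleStrata, seed) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1)
    stopf("'fraction' must be in (0, 1)")
  if (length(eligibleStrata) == 0L)
    stopf("'eligibleStrata' must be non-empty")
  s <- subjects(cohort)
  eligible <- s$design == "population" & s$stratum %in% eligibleStrata
  if (!any(eligible)) stopf("no eligible subjects for validation sampling")
  idx <- which(eligible)
  cell <- interaction(s$stratum[idx], s$status[idx], drop = TRUE)
  valIdx <- withSeed(seed, {
    unlist(lapply(split(idx, cell), function(ii) {
      k <- round(fraction * length(ii))
      if (k == 0L) integer(0) else ii[sample.int(length(ii), k)]
    }), use.names = FALSE)
  })
  inVal <- logical(nrow(s))
  inVal[valIdx] <- TRUE
  training <- Cohort(s[!inVal, , drop = FALSE], variants(cohort),
                     metadata = cohort@metadata)
  validation <- Cohort(s[inVal, , drop = FALSE], variants(cohort),
                       metadata = cohort@metadata)
  list(training = training, validation = validation)
}

#' Filter subjects by carriage rules
#'
#' Removes subjects carrying a PTV in any of the listed genes (the standard
#' exclusion for all analyses except the mixture models, which re-include
#' them) and, optionally, subjects carrying more than one eligible missense
#' variant within a single gene. A removal log (counts per reason) is
#' attached to the returned cohort's metadata as `removal_log`.
#'
#' @param cohort a Cohort.
#' @param dropPtvCarriersIn character vector of gene symbols (may be empty).
#' @param dropMultiMissenseGenes logical; drop subjects with >= 2 missense
#'   variants of the same gene.
#' @return filtered Cohort with `metadata(...)$removal_log`.
#' @export
filterSubjects <- function(cohort, dropPtvCarriersIn = character(0),
                           dropMultiMissenseGenes = FALSE) {
  s <- subjects(cohort)
  v <- variants(cohort)
  geneOf <- setNames(v$gene, v$variant_id)
  consOf <- setNames(v$consequence, v$variant_id)
  dropPtv <- vapply(s$carried, function(ids) {
    any(consOf[ids] == "PTV" & geneOf[ids] %in% dropPtvCarriersIn)
  }, logical(1L))
  dropMulti <- if (dropMultiMissenseGenes) {
    vapply(s$carried, function(ids) {
      mis <- ids[consOf[ids] == "missense"]
      length(mis) > 1L && anyDuplicated(geneOf[mis]) > 0L
    }, logical(1L))
  } else rep(FALSE, nrow(s))
  keep <- !(dropPtv | dropMulti)
  log <- list(ptv_carrier = sum(dropPtv),
              multi_missense = sum(dropMulti & !dropPtv),
              retained = sum(keep))
  md <- cohort@metadata
  md$removal_log <- log
  Cohort(s[keep, , drop = FALSE], v, metadata = md)
}

#' Write a named set of result tables as TSV files
#'
#' One TSV per table, full numeric precision (15 significant digits), plus a
#' JSON manifest listing each file and its row count.
#'
#' @param tables named list of data.frames.
#' @param outDir output directory (created if needed).
#' @return data.frame manifest (name, path, rows), also written to
#'   `manifest.json` in `outDir`.
#' @export
writeReport <- function(tables, outDir) {
  stopifnot(is.list(tables))
  if (length(tables) && (is.null(names(tables)) || any(!nzchar(names(tables)))))
    stopf("'tables' must be a named list")
  if (!dir.exists(outDir)) {
    ok <- dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stopf("cannot create output directory '%s'", outDir)
  }
  entries <- lapply(names(tables), function(nm) {
    tb <- as.data.frame(tables[[nm]])
    path <- file.path(outDir, paste0(nm, ".tsv"))
    num <- vapply(tb, is.numeric, logical(1L))
    out <- tb
    out[num] <- lapply(tb[num], function(x) format(x, digits = 15, trim = TRUE))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
    data.frame(name = nm, path = path, rows = nrow(tb),
               stringsAsFactors = FALSE)
  })
  manifest <- if (length(entries)) do.call(rbind, entries) else
    data.frame(name = character(0), path = character(0), rows = integer(0))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  manifest
}

#' @rdname Cohort-class
#' @export
metadata <- function(x) x@metadata
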