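# Internal per-subject carriage classification for one gene.
#
# Returns, for each subject: whether they carry a PTV in the gene, how many
# eligible missense variants of the gene they carry, and (for single
# carriers) which variant. Subjects carrying both a PTV and a missense
# variant in the gene are classified as PTV carriers (their missense
# carriage is ignored). Vectorized over the carried list column.
geneCarriage <- function(cohort, gene, eligibleIds) {
  s <- subjects(cohort)
  v <- variants(cohort)
  carried <- s$carried
  n <- nrow(s)
  ids <- unlist(carried, use.names = FALSE)
  subj <- rep.int(seq_len(n), lengths(carried))
  row <- match(ids, v$variant_id)
  isPtv <- v$consequence[row] == "PTV" & v$gene[row] == gene
  isElig <- ids %in% eligibleIds

  ptv <- logical(n)
  ptv[subj[isPtv]] <- TRUE
  nElig <- tabulate(subj[isElig], nbins = n)
  variantOf <- rep(NA_character_, n)
  single <- which(nElig == 1L & !ptv)
  hit <- isElig & subj %in% single
  variantOf[subj[hit]] <- ids[hit]
  list(ptv = ptv, nEligible = nElig, variantOf = variantOf,
       multi = nElig >= 2L & !ptv)
}

# counts per (variant x stratum x status) plus non-carrier and PTV margins
mixtureCounts <- function(cohort, assignment, includePtv = TRUE) {
  gene <- assignment@gene
  mapping <- assignment@mapping
  s <- subjects(cohort)
  carr <- geneCarriage(cohort, gene, names(mapping))
  strat <- factor(s$stratum,
                  levels = names(sort(table(s$stratum), decreasing = TRUE)))
  isCase <- s$status == "case"

  keep <- !carr$multi
  if (!includePtv) keep <- keep & !carr$ptv
  excludedMulti <- sum(carr$multi)

  useP <- keep & carr$ptv
  useV <- keep & !carr$ptv & !is.na(carr$variantOf)
  useN <- keep & !carr$ptv & is.na(carr$variantOf)

  S <- nlevels(strat)
  tab2 <- function(sel) {
    m <- matrix(0, 2L, S, dimnames = list(c("case", "control"), levels(strat)))
    t1 <- table(factor(ifelse(isCase[sel], "case", "control"),
                       levels = c("case", "control")), strat[sel])
    m[, colnames(t1)] <- t1
    m
  }
  nc <- tab2(useN)
  pt <- tab2(useP)

  vIdx <- which(useV)
  vf <- factor(carr$variantOf[vIdx], levels = unique(carr$variantOf[vIdx]))
  carriedIds <- levels(vf)
  Vcase <- matrix(0, length(carriedIds), S,
                  dimnames = list(carriedIds, levels(strat)))
  Vctl <- Vcase
  if (length(vIdx)) {
    tc <- table(vf[isCase[vIdx]], strat[vIdx][isCase[vIdx]])
    Vcase[rownames(tc), colnames(tc)] <- tc
    tl <- table(vf[!isCase[vIdx]], strat[vIdx][!isCase[vIdx]])
    Vctl[rownames(tl), colnames(tl)] <- tl
  }
  fp <- paste(nrow(s), sum(isCase), sum(nchar(s$subject_id)),
              sum(utf8ToInt(paste(sort(s$subject_id), collapse = ""))),
              sep = ":")
  list(gene = gene, strata = levels(strat),
       ncCase = nc["case", ], ncCtl = nc["control", ],
       ptvCase = pt["case", ], ptvCtl = pt["control", ],
       Vcase = Vcase, Vctl = Vctl,
       category = unname(mapping[carriedIds]),
       carriedIds = carriedIds,
       allIds = names(mapping), allCats = unname(mapping),
       excludedMulti = excludedMulti,
       nPtvCarriers = sum(useP), fingerprint = fp)
}
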