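## Label lookup helper: states is the classifyCell() output for family cells.
.stateLookup <- function(states) {
  key <- paste(states$cell_id, states$chrom, states$haplotype, sep = "\r")
  lab <- setNames(as.character(states$label), key)
  function(cell, chrom, hap) {
    v <- lab[paste(cell, chrom, hap, sep = "\r")]
    ifelse(is.na(v), NA_character_, v)
  }
}

.otherHap <- function(h) setdiff(c("A", "B"), h)

## One scored scenario: constraints are (satisfied, weight) pairs; `detected`
## marks whether the scenario's definitive observation (near-complete
## transcriptional loss, or the reduced MN haplotype) is present at all.
.scoreConstraints <- function(cons) {
  sat <- vapply(cons, function(x) isTRUE(x$ok), logical(1))
  w <- vapply(cons, function(x) x$w, numeric(1))
  req <- vapply(cons, function(x) isTRUE(x$required), logical(1))
  list(score = sum(w[sat]), max = sum(w),
       detected = all(sat[req]) && any(req))
}

#' Enumerate and score segregation scenarios for one family
#'
#' Every (chromosome, haplotype, pattern) candidate is scored by the number of
#' satisfied role constraints, with near-silent "0" detections weighted twice
#' (transcriptional loss in a non-MN cell is the most definitive signature).
#' Micronucleus-independent reciprocal gain/loss between siblings is scored as
#' a competing explanation. A candidate is \emph{detected} only when its
#' definitive constraint holds; candidates never constrain the MN chromatid's
#' own transcription level, which keeps the inference independent of whether
#' the MN chromosome is silenced.
#'
#' @param states DataFrame from \code{\link{classifyCell}} for all family
#'   cells (>= 2 cells).
#' @param roles Named character vector: cell_id -> role.
#' @param generation 1 or 2.
#' @return DataFrame: chrom, haplotype, pattern, type (mn/reciprocal), score,
#'   max_score, detected.
#' @export
enumerateScenarios <- function(states, roles, generation) {
  cells <- unique(states$cell_id)
  if (length(cells) < 2) stop("family must contain >= 2 classified cells")
  L <- .stateLookup(states)
  chroms <- unique(states$chrom)
  mn <- names(roles)[roles == "mn_cell"]
  sis <- names(roles)[roles == "mn_sister"]
  dtr <- names(roles)[roles == "mn_daughter"]
  nie <- names(roles)[roles == "mn_niece"]
  acc <- new.env(parent = emptyenv())
  acc$chrom <- character(0); acc$hap <- character(0)
  acc$pattern <- character(0); acc$type <- character(0)
  acc$score <- numeric(0); acc$max <- numeric(0); acc$det <- logical(0)
  add <- function(ch, h, pattern, type, sc) {
    acc$chrom <- c(acc$chrom, ch); acc$hap <- c(acc$hap, h)
    acc$pattern <- c(acc$pattern, pattern); acc$type <- c(acc$type, type)
    acc$score <- c(acc$score, sc$score); acc$max <- c(acc$max, sc$max)
    acc$det <- c(acc$det, sc$detected)
  }
  for (ch in chroms) {
    for (h in c("A", "B")) {
      o <- .otherHap(h)
      if (generation == 1L && length(mn) && length(sis)) {
        sc <- .scoreConstraints(list(
          list(ok = L(sis, ch, h) == "0", w = 2, required = TRUE),
          list(ok = L(sis, ch, o) == "1", w = 1),
          list(ok = L(mn, ch, o) == "1", w = 1),
          list(ok = L(mn, ch, h) != "0", w = 1)))
        add(ch, h, "1:3", "mn", sc)
        mnLab <- L(mn, ch, h)
        sc <- .scoreConstraints(list(
          list(ok = mnLab %in% c("0", "1-"),
               w = if (identical(unname(mnLab), "0")) 2 else 1,
               required = TRUE),
          list(ok = L(sis, ch, h) == "1", w = 1),
          list(ok = L(sis, ch, o) == "1", w = 1),
          list(ok = L(mn, ch, o) == "1", w = 1)))
        add(ch, h, "2:2", "mn", sc)
        ## reciprocal, MN-independent gain/loss between the siblings
        for (pair in list(c(mn, sis), c(sis, mn))) {
          sc <- .scoreConstraints(list(
            list(ok = L(pair[1], ch, h) == "0", w = 2, required = TRUE),
            list(ok = L(pair[2], ch, h) == "2", w = 1, required = TRUE),
            list(ok = L(pair[1], ch, o) == "1", w = 1),
            list(ok = L(pair[2], ch, o) == "1", w = 1)))
          add(ch, h, "reciprocal", "reciprocal", sc)
        }
      }
      if (generation == 2L && length(dtr) >= 2) {
        d1 <- dtr[1]; d2 <- dtr[2]
        haveNieces <- length(nie) >= 2
        ## 1:3 in generation 1: nieces nullisomic, daughters carry >= 1 copy
        cons <- list()
        if (haveNieces) {
          cons <- c(cons, lapply(nie, function(nc)
            list(ok = L(nc, ch, h) == "0", w = 2, required = TRUE)))
          cons <- c(cons, lapply(nie, function(nc)
            list(ok = L(nc, ch, o) == "1", w = 1)))
        } else {
          ## without nieces: an extra, transcribing copy in >= 1 daughter
          ## (the 3:2 / 2:1 imbalance template)
          cons <- c(cons, list(list(
            ok = any(c(L(d1, ch, h), L(d2, ch, h)) %in% c("1+", "2")),
            w = 1, required = TRUE)))
        }
        cons <- c(cons,
                  list(list(ok = L(d1, ch, h) != "0", w = 1),
                       list(ok = L(d2, ch, h) != "0", w = 1),
                       list(ok = L(d1, ch, o) == "1", w = 1),
                       list(ok = L(d2, ch, o) == "1", w = 1)))
        add(ch, h, "1:3", "mn", .scoreConstraints(cons))
        ## 2:2 in generation 1: single MN chromatid split across daughters
        dl <- c(L(d1, ch, h), L(d2, ch, h))
        cons <- list(
          list(ok = any(dl %in% c("0", "1-")),
               w = if (any(dl == "0", na.rm = TRUE)) 2 else 1,
               required = TRUE),
          list(ok = all(dl %in% c("0", "1-", "1")), w = 1),
          list(ok = L(d1, ch, o) == "1", w = 1),
          list(ok = L(d2, ch, o) == "1", w = 1))
        if (haveNieces) {
          cons <- c(cons, lapply(nie, function(nc)
            list(ok = L(nc, ch, h) == "1", w = 1)))
          cons <- c(cons, lapply(nie, function(nc)
            list(ok = L(nc, ch, o) == "1", w = 1)))
        }
        add(ch, h, "2:2", "mn", .scoreConstraints(cons))
        ## reciprocal gain/loss within the daughter (or niece) pair
        pairs <- list(c(d1, d2), c(d2, d1))
        if (haveNieces) pairs <- c(pairs, list(nie[1:2], nie[2:1]))
        for (pair in pairs) {
          sc <- .scoreConstraints(list(
            list(ok = L(pair[1], ch, h) == "0", w = 2, required = TRUE),
            list(ok = L(pair[2], ch, h) == "2", w = 1, required = TRUE),
            list(ok = L(pair[1], ch, o) == "1", w = 1),
            list(ok = L(pair[2], ch, o) == "1", w = 1)))
          add(ch, h, "reciprocal", "reciprocal", sc)
        }
      }
    }
  }
  DataFrame(chrom = acc$chrom, haplotype = acc$hap, pattern = acc$pattern,
            type = acc$type, score = acc$score, max_score = acc$max,
            detected = acc$det)
}

#' Infer the micronucleus chromosome of one family
#'
#' Accepts the highest-scoring detected scenario when it is unique. Families
#' with no flagged homologue anywhere are reported as invisible-normal (a 2:2
#' segregation with normal MN transcription is indistinguishable from a normal
#' karyotype). Exact score ties are reported as unresolved with all tied
#' candidates listed — with two exceptions: a reciprocal explanation tying
#' with a micronucleus scenario on the same homologue defers to the
#' micronucleus scenario (the family is known to be micronucleated), unless
#' another homologue elsewhere carries a defective (reduced) pattern that the
#' micronucleus scenario would leave unexplained, in which case that homologue
#' is preferred.
#'
#' @param states DataFrame from \code{\link{classifyCell}} for family cells.
#' @param roles Named character vector: cell_id -> role.
#' @param generation 1 or 2.
#' @param familyId Family identifier for the report.
#' @return An \linkS4class{MNAssignment}.
#' @export
inferMNChromosome <- function(states, roles, generation, familyId = "F") {
  cand <- enumerateScenarios(states, roles, generation)
  nieces <- any(roles == "mn_niece")
  conf <- if (generation == 1L || nieces) "direct" else
    "inferred-without-nieces"
  anyFlag <- any(states$flagged)
  det <- cand[cand$detected, , drop = FALSE]
  emptyCall <- function(confidence, notes) {
    new("MNAssignment", familyId = familyId, chromosome = NA_character_,
        haplotype = NA_character_, pattern = NA_character_,
        generation = as.integer(generation), confidence = confidence,
        score = 0, candidates = cand, notes = notes)
  }
  if (nrow(det) == 0) {
    if (!anyFlag) {
      return(emptyCall("invisible-normal",
                       "no significant deviation in any cell; consistent with a 2:2 segregation with normal MN transcription"))
    }
    return(emptyCall("unresolved",
                     "flagged homologues present but no coherent segregation scenario"))
  }
  top <- det[det$score == max(det$score), , drop = FALSE]
  mnTop <- top[top$type == "mn", , drop = FALSE]
  notes <- ""
  if (nrow(top) > 1) {
    key <- unique(paste(top$chrom, top$haplotype))
    if (nrow(mnTop) >= 1 && length(unique(paste(mnTop$chrom, mnTop$haplotype,
                                                mnTop$pattern))) == 1 &&
        all(paste(top$chrom, top$haplotype) %in%
            paste(mnTop$chrom, mnTop$haplotype))) {
      ## reciprocal tie on the same homologue: keep the MN scenario
      top <- mnTop[1, , drop = FALSE]
      notes <- "micronucleus-independent reciprocal mis-segregation is an equally consistent alternative"
    } else if (length(key) > 1 && nrow(mnTop) >= 1) {
      ## prefer the MN candidate that leaves no defective homologue
      ## unexplained: a tied reciprocal plus a separate reduced homologue
      reduced <- states[states$label %in% c("0", "1-"), , drop = FALSE]
      expl <- vapply(seq_len(nrow(mnTop)), function(i) {
        any(reduced$chrom == mnTop$chrom[i] &
              reduced$haplotype == mnTop$haplotype[i])
      }, logical(1))
      if (sum(expl) == 1) {
        top <- mnTop[expl, , drop = FALSE]
        notes <- "tie broken toward the scenario explaining the defective homologue"
      } else {
        return(emptyCall("unresolved", paste(
          "tied candidates:",
          paste(sprintf("%s-%s (%s)", top$chrom, top$haplotype, top$pattern),
                collapse = ", "))))
      }
    } else {
      return(emptyCall("unresolved", paste(
        "tied candidates:",
        paste(sprintf("%s-%s (%s)", top$chrom, top$haplotype, top$pattern),
              collapse = ", "))))
    }
  }
  if (top$type[1] == "reciprocal") {
    return(emptyCall("unresolved",
                     sprintf("best explanation is micronucleus-independent reciprocal mis-segregation at %s-%s",
                             top$chrom[1], top$haplotype[1])))
  }
  new("MNAssignment", familyId = familyId, chromosome = top$chrom[1],
      haplotype = top$haplotype[1], pattern = top$pattern[1],
      generation = as.integer(generation), confidence = conf,
      score = top$score[1], candidates = cand, notes = notes)
}

#' Estimate the MN chromatid's transcriptional yield
#'
#' The estimation basis follows the inferred scenario. Generation 1, 2:2: the
#' MN haplotype's yield in the MN cell \emph{is} the chromatid yield
#' (direct-2:2). Generation 1, 1:3: the MN haplotype carries an intact copy
#' plus the chromatid, so the yield is compared with the two-copy reference
#' and the chromatid yield is the excess over the one-copy mean
#' (vs-disomic-3:1). Generation 2, 2:2: the chromatid may fragment across both
#' daughters, so their MN-haplotype yields are summed (combined-daughters).
#' Generation 2, 1:3: each daughter carries an intact copy plus a chromatid
#' share; each daughter is compared with the one-copy and two-copy references
#' and the summed excess over the one-copy mean is reported
#' (per-daughter-vs-mono-and-di). Classification reuses the z machinery:
#' near-silent below the nullisomic bound, normal when consistent with the
#' scenario's normal expectation, reduced otherwise.
#'
#' @param summaries DataFrame from \code{\link{cellSummaries}} for the family.
#' @param assignment \linkS4class{MNAssignment}.
#' @param roles Named character vector: cell_id -> role.
#' @param ref \linkS4class{ReferenceDistribution}.
#' @param aneuRef \linkS4class{AneuploidReference}.
#' @param alpha Significance level on Bonferroni-corrected p (default 0.05).
#' @param nTests Bonferroni family size, matching the per-cell classification
#'   (default: homologues per cell in \code{summaries}).
#' @return An \linkS4class{MNYieldEstimate}.
#' @export
estimateMNYield <- function(summaries, assignment, roles, ref, aneuRef,
                            alpha = 0.05, nTests = NULL) {
  if (assignment@confidence == "invisible-normal") {
    return(new("MNYieldEstimate", a = NA_real_, basis = "none",
               classification = "consistent-with-normal",
               p = numeric(0), details = list()))
  }
  if (assignment@confidence == "unresolved") {
    stop("cannot estimate the MN yield of an unresolved assignment")
  }
  ch <- assignment@chromosome
  h <- assignment@haplotype
  if (is.null(nTests)) {
    nTests <- 2L * length(unique(summaries$chrom))
  }
  zp <- function(x, mu, sigma) {
    bonferroniCorrect(zTestTwoTailed(x, mu, sigma), nTests)
  }
  rs <- referenceStats(ref)
  ri <- which(rs$chrom == ch & rs$haplotype == h)
  muM <- rs$mu[ri]; sgM <- rs$sigma[ri]
  tri <- aneuRef@trisomic
  ti <- match(sub("[pq]$", "", ch), tri$chrom)
  if (is.na(ti)) ti <- match(ch, tri$chrom)
  muD <- tri$mu[ti]; sgD <- tri$sigma[ti]
  nb <- aneuRef@nullisomicBound
  yOf <- function(cell) {
    row <- summaries[summaries$cell_id == cell & summaries$chrom == ch, ]
    if (h == "A") row$y_A else row$y_B
  }
  gen <- assignment@generation
  pat <- assignment@pattern
  if (gen == 1L && pat == "2:2") {
    y <- yOf(names(roles)[roles == "mn_cell"])
    pM <- zp(y, muM, sgM)
    cls <- if (y < nb) "near-silent" else if (pM >= alpha) "normal" else
      "reduced"
    return(new("MNYieldEstimate", a = max(0, y), basis = "direct-2:2",
               classification = cls, p = c(p_mono = pM),
               details = list(y_mn = y)))
  }
  if (gen == 1L && pat == "1:3") {
    y <- yOf(names(roles)[roles == "mn_cell"])
    a <- max(0, y - muM)
    pD <- zp(y, muD, sgD)
    pM <- zp(y, muM, sgM)
    cls <- if (a < nb && pM >= alpha) "near-silent" else
      if (pD >= alpha) "normal" else "reduced"
    return(new("MNYieldEstimate", a = a, basis = "vs-disomic-3:1",
               classification = cls, p = c(p_mono = pM, p_di = pD),
               details = list(y_mn = y)))
  }
  dtr <- names(roles)[roles == "mn_daughter"]
  yD <- vapply(dtr, yOf, numeric(1))
  if (pat == "2:2") {
    a <- max(0, sum(yD))
    sgC <- sqrt(2) * sgM
    pC <- zp(sum(yD), muM, sgC)
    cls <- if (a < nb) "near-silent" else if (pC >= alpha) "normal" else
      "reduced"
    return(new("MNYieldEstimate", a = a, basis = "combined-daughters",
               classification = cls, p = c(p_combined = pC),
               details = list(y_daughters = yD)))
  }
  ## generation 2, 1:3: each daughter holds an intact copy plus a share
  a <- max(0, sum(yD - muM))
  pM <- zp(yD, muM, sgM)
  pD <- zp(yD, muD, sgD)
  ## normal expectation: total excess over the two intact copies is one
  ## chromatid's worth (the one-copy mean); under that hypothesis one
  ## daughter transcribes near the two-copy level, so the combined
  ## dispersion mixes both reference sigmas
  cls <- if (a < nb) "near-silent" else
    if (zp(a, muM, sqrt(sgM^2 + sgD^2)) >= alpha) "normal" else
      "reduced"
  names(pM) <- paste0("p_mono_", seq_along(pM))
  names(pD) <- paste0("p_di_", seq_along(pD))
  new("MNYieldEstimate", a = a, basis = "per-daughter-vs-mono-and-di",
      classification = cls, p = c(pM, pD),
      details = list(y_daughters = yD))
}
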