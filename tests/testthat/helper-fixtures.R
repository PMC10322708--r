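# Shared fixtures: one small genome, one control cohort and the references
# derived from it. Built once per test run; all tests that need a calibrated
# background reuse these instead of re-simulating.

.fx <- local({
  catalog <- generateGeneCatalog(nChromosomes = 5, chromLength = 1e8,
                                 genesPerChromosome = 100, seed = 1)
  controls <- simulateControls(catalog, nControl = 30, depth = 100, seed = 2)
  controlIds <- SummarizedExperiment::colData(controls)$cell_id
  retained <- geneFilters(controls, controlIds)
  ctrlSummaries <- cellSummaries(controls, controls, retained = retained)
  reference <- buildReference(ctrlSummaries)
  aneuploid <- buildAneuploidReference(ctrlSummaries)
  list(catalog = catalog, controls = controls, controlIds = controlIds,
       retained = retained, ctrlSummaries = ctrlSummaries,
       reference = reference, aneuploid = aneuploid)
})

# Run one family end to end against the shared background.
runFamily <- function(scenario, seed, includeNieces = TRUE) {
  sim <- simulateFamily(.fx$catalog, scenario, nControl = 0, depth = 100,
                        seed = seed, includeNieces = includeNieces)
  famSum <- cellSummaries(sim$family, .fx$controls, retained = .fx$retained)
  states <- classifyCell(famSum, .fx$reference, .fx$aneuploid)
  roles <- cellRoles(sim$family)
  assignment <- inferMNChromosome(states, roles, scenario$generation, "Ftest")
  yield <- if (assignment@confidence %in% c("direct",
                                            "inferred-without-nieces",
                                            "invisible-normal")) {
    estimateMNYield(famSum, assignment, roles, .fx$reference, .fx$aneuploid)
  }
  list(family = sim$family, summaries = famSum, states = states,
       roles = roles, assignment = assignment, yield = yield)
}

# Independent Fisher oracle: enumerate every table with the observed margins
# and sum the probabilities of those no more likely than the observed table.
fisherByEnumeration <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  aRange <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(aRange, r1, r2, c1)
  pObs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Hand-built state table for constructing exact classifier outputs.
makeStates <- function(cells, chroms = paste0("chr", 1:5),
                       labels = NULL) {
  grid <- expand.grid(haplotype = c("A", "B"), chrom = chroms,
                      cell_id = cells, stringsAsFactors = FALSE)
  st <- S4Vectors::DataFrame(cell_id = grid$cell_id, chrom = grid$chrom,
                             haplotype = grid$haplotype,
                             yield = 0.5, label = "1",
                             p_mono = 1, p_di = 0, flagged = FALSE)
  if (!is.null(labels)) {
    for (k in seq_len(nrow(labels))) {
      i <- st$cell_id == labels$cell_id[k] & st$chrom == labels$chrom[k] &
        st$haplotype == labels$haplotype[k]
      st$label[i] <- labels$label[k]
      st$flagged[i] <- labels$label[k] != "1"
      st$yield[i] <- labels$yield[k]
    }
  }
  st
}
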