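# Shared fixtures and oracle helpers, built in code at test time.

# Intensity pair with a prescribed raw (G = 1) GP at a given total.
pairWithRawGP <- function(gp, total = 1000) {
  c(ordered = total * (1 + gp) / 2, disordered = total * (1 - gp) / 2)
}

# Direct recomputation of mean GP from generated count arrays (the oracle
# for generator-recovery checks; independent of gpMap's masking logic).
oracleMeanGP <- function(field, cellIdx = seq_along(field$masks)) {
  io <- orderedChannel(field$channels)
  id <- disorderedChannel(field$channels)
  vapply(cellIdx, function(i) {
    m <- field$masks[[i]]
    mean(((io - id) / (io + id))[m])
  }, numeric(1))
}

# Wide per-sample feature table from a long RQ table.
rqWide <- function(rq) {
  wide <- stats::reshape(rq[, c("sample", "phenotype", "gene", "value")],
                         idvar = c("sample", "phenotype"), timevar = "gene",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide
}

# Elevation set for one feature versus the M0 comparator.
elevatedSet <- function(profile, feature) {
  calls <- profile$calls
  featCol <- intersect(c("marker", "gene"), names(calls))[1]
  sort(calls$phenotype[calls[[featCol]] == feature &
                         calls$comparator == "M0"])
}

# One qualitative-profile replicate for the study's marker/expression
# structure; returns named logicals, one per profile check.
profileChecks <- function(seed, alpha = 0.05) {
  mp <- markerProfile(simMfiTable(seed = seed), alpha = alpha)
  cd86_12 <- mp$comparisons[mp$comparisons$marker == "CD86" &
                              mp$comparisons$group_a %in% c("M1", "M2") &
                              mp$comparisons$group_b %in% c("M1", "M2"), ]
  ep <- expressionProfile(
    simExpressionTable(SyntheticExpressionSpec(seed = seed)), alpha = alpha)
  il10_12 <- ep$comparisons[ep$comparisons$gene == "IL10" &
                              ep$comparisons$group_a == "M1" &
                              ep$comparisons$group_b == "M2", ]
  c(cd64_only_m1  = identical(elevatedSet(mp, "CD64"), "M1"),
    cd206_only_m2 = identical(elevatedSet(mp, "CD206"), "M2"),
    cd86_m1_m2    = identical(elevatedSet(mp, "CD86"), c("M1", "M2")),
    cd86_m1_vs_m2_ns = nrow(cd86_12) == 1 && cd86_12$p >= alpha,
    il1b_up_m1    = "M1" %in% elevatedSet(ep, "IL1B"),
    il6_up_m1     = "M1" %in% elevatedSet(ep, "IL6"),
    il10_up_m2    = nrow(il10_12) == 1 && il10_12$p < alpha &&
                      il10_12$mean_diff > 0)
}
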