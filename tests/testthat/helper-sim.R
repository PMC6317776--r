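# Shared fixture builders. Everything is generated in code; no binary data.

makeInstrument <- function(bx, by, sx = rep(0.01, length(bx)),
                           sy = rep(0.02, length(bx)), ...) {
  HarmonizedInstrument(sprintf("rs%03d", seq_along(bx)), bx, sx, by, sy, ...)
}

writeTSV <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

sumstatsRow <- function(rsid, ea, oa, beta, se, eaf = NA_real_,
                        pval = NA_real_, info = NA_real_) {
  data.frame(rsid = rsid, chrom = "1", pos = 1L, effect_allele = ea,
             other_allele = oa, eaf = eaf, beta = beta, se = se,
             pval = pval, info = info, n = NA_integer_,
             stringsAsFactors = FALSE)
}

# Rebuild exposure/outcome tables from a harmonized instrument, expressed
# on the exposure's alleles (used for idempotence checks).
instrumentToTables <- function(inst, exposure) {
  ix <- match(snps(inst), exposure$rsid)
  exp2 <- exposure[ix, , drop = FALSE]
  exp2$beta <- betaExposure(inst)
  exp2$se <- seExposure(inst)
  out2 <- exp2
  out2$beta <- betaOutcome(inst)
  out2$se <- seOutcome(inst)
  rownames(exp2) <- rownames(out2) <- NULL
  list(exposure = exp2, outcome = out2)
}
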