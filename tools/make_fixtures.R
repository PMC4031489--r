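# Generates the plain-text fixtures under inst/extdata from the table data
# reconstructed in code. Run once; outputs are committed.
out <- "inst/extdata"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# ---- annotation table (23 family variants + 2 pair-only + 6 synthetic) ----
ann <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
gene chrom pos ref alt cdna_change protein_change functional_class known_id maf_ESP6500 maf_1000G sift polyphen_hvar sanger_confirmed
SRA1 chr5 139936828 C T c.C91T p.P31S nonsynonymous_SNV NA NA NA 0.00 1.00 TRUE
PHKG2 chr16 30767746 C T c.C706T p.R236W nonsynonymous_SNV NA NA NA 0.00 1.00 TRUE
ZNF24 chr18 32919897 T G c.T464G p.M155R nonsynonymous_SNV NA NA NA 0.02 0.00 TRUE
TMPRSS7 chr3 111797705 G A c.G1963A p.G655S nonsynonymous_SNV NA NA NA 0.00 1.00 TRUE
ABLIM2 chr4 8055946 G A c.G791A p.R264Q nonsynonymous_SNV NA NA NA 0.05 1.00 TRUE
FOXP1 chr3 71247489 C T c.C44T p.A15V nonsynonymous_SNV NA NA NA 0.34 0.98 TRUE
GSTK1 chr7 142964824 G A c.G703A p.G235R nonsynonymous_SNV NA NA NA 0.02 1.00 TRUE
LACRT chr12 55028594 C T c.C32T p.A11V nonsynonymous_SNV NA NA NA 0.00 0.99 TRUE
PAMR1 chr11 35456266 G A c.G1420A p.G474R nonsynonymous_SNV NA NA NA 0.00 1.00 TRUE
TTN chr2 179400887 G A c.G73392A p.W24464X stopgain NA NA NA NA NA TRUE
UEVLD chr11 18553971 G T c.G1312T p.V438L nonsynonymous_SNV rs143160739 0.0005 NA 0.37 0.96 TRUE
ITGA1 chr5 52240783 C G c.C3296G p.S1099C nonsynonymous_SNV rs370052455 0.0008 NA 0.01 1.00 TRUE
BPTF chr17 65850386 A C c.A944C p.N315T nonsynonymous_SNV NA NA NA 0.00 1.00 TRUE
CACNB3 chr12 49220218 G A c.G688A p.A230T nonsynonymous_SNV NA NA NA 0.01 1.00 TRUE
CUL4B chrX 119680410 A T c.A838T p.R280X stopgain NA NA NA NA NA TRUE
SEMA3C chr7 80374250 G A c.G2216A p.R739Q nonsynonymous_SNV NA NA NA 0.01 0.99 TRUE
TBC1D22B chr6 37280778 G A c.G1067A p.S356N nonsynonymous_SNV NA NA NA 0.03 0.39 TRUE
CHCHD1 chr10 75541868 G T c.G35T p.R12L nonsynonymous_SNV NA NA NA 0.01 0.99 TRUE
KCTD8 chr4 44177010 C T c.C1219T p.R407C nonsynonymous_SNV NA NA NA 0.00 1.00 TRUE
CLCN4 chrX 10176455 G A c.G1214A p.C405Y nonsynonymous_SNV NA NA NA 0.00 0.98 TRUE
LAT chr16 29000901 G T c.G634T p.A212S nonsynonymous_SNV NA NA NA 0.02 1.00 TRUE
ZNF304 chr19 57868409 A T c.A1172T p.Y391F nonsynonymous_SNV NA NA NA 0.16 1.00 TRUE
ZNF674 chrX 46359537 C A c.C1487A p.P496H nonsynonymous_SNV NA NA NA 0.00 1.00 TRUE
RAB3C chr5 58147140 G A c.G646A p.E216K nonsynonymous_SNV NA NA NA 0.01 0.99 TRUE
CASQ1 chr1 160165804 G A c.G769A p.E257K nonsynonymous_SNV NA NA NA 0.01 0.99 TRUE
SYNBG1 chr1 1000000 A G NA NA nonsynonymous_SNV rs900000001 0.24 0.25 0.80 0.10 NA
SYNBG2 chr2 2000000 C T NA NA nonsynonymous_SNV NA NA NA 0.01 0.99 NA
SYNBG3 chr3 3000000 G A NA NA synonymous NA NA NA NA NA NA
SYNBG4 chr4 4000000 T C NA NA nonsynonymous_SNV rs900000002 0.005 NA 0.01 0.99 NA
SYNBG5 chr5 5000000 A T NA NA nonsynonymous_SNV NA NA NA 0.50 0.20 NA
SYNBG6 chr6 6000000 C G NA NA nonsynonymous_SNV NA NA NA 0.00 1.00 NA
")
write.table(ann, file.path(out, "family_annotations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE, na = "NA")

# ---- full-family presence matrix (reconstructed; frequency-consistent) ----
carriers <- list(
  SRA1 = c(1, 2, 4, 5, 6, 7, 8), PHKG2 = c(1, 2, 4, 6, 7),
  ZNF24 = c(1, 4, 5, 6), TMPRSS7 = c(1, 2, 5, 6),
  ABLIM2 = c(2, 4, 7), FOXP1 = c(2, 4, 7), GSTK1 = c(1, 2, 6),
  LACRT = c(1, 4, 5), PAMR1 = c(1, 2, 5), TTN = c(2, 4, 7),
  UEVLD = c(1, 2), ITGA1 = c(1, 2),
  BPTF = 5, CACNB3 = 2, CUL4B = 5, SEMA3C = 5, TBC1D22B = 5,
  CHCHD1 = 2, KCTD8 = 5, CLCN4 = 5, LAT = 5, ZNF304 = 5, ZNF674 = 5,
  SYNBG1 = 1:8, SYNBG2 = c(1, 3), SYNBG3 = c(2, 4), SYNBG4 = 2,
  SYNBG5 = 4, SYNBG6 = c(9, 5)
)
samples <- as.character(1:10)
genes <- names(carriers)
stopifnot(all(genes %in% ann$gene))
m <- matrix(0L, length(genes), length(samples),
            dimnames = list(genes, samples))
for (g in genes) m[g, as.character(carriers[[g]])] <- 1L
pres <- data.frame(gene = genes,
                   ann[match(genes, ann$gene), c("chrom", "pos", "ref", "alt")],
                   m, check.names = FALSE)
names(pres)[6:15] <- paste0("S", samples)
write.table(pres, file.path(out, "family_presence_synthetic.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# sanity: frequencies over affected members 1,2,4,5,6,7 for the 23
aff <- c("1", "2", "4", "5", "6", "7")
freq <- rowSums(m[1:23, aff])
expected <- c(SRA1 = 6, PHKG2 = 5, ZNF24 = 4, TMPRSS7 = 4, ABLIM2 = 3,
              FOXP1 = 3, GSTK1 = 3, LACRT = 3, PAMR1 = 3, TTN = 3,
              UEVLD = 2, ITGA1 = 2, BPTF = 1, CACNB3 = 1, CUL4B = 1,
              SEMA3C = 1, TBC1D22B = 1, CHCHD1 = 1, KCTD8 = 1, CLCN4 = 1,
              LAT = 1, ZNF304 = 1, ZNF674 = 1)
stopifnot(identical(freq[names(expected)], expected))
stopifnot(sum(freq) == 52)

# ---- generation-pair presence matrix (mother/daughter tables) ----
pair_carriers <- list(
  RAB3C = c(2, 5, 6), SRA1 = c(2, 5, 6, 4, 7, 8), TMPRSS7 = c(2, 5, 6),
  ZNF24 = c(2, 5, 6), LACRT = c(2, 5), PAMR1 = c(2, 5), GSTK1 = c(2, 6),
  PHKG2 = c(2, 6, 4, 7), UEVLD = c(2, 6), ITGA1 = 2, BPTF = 5,
  TBC1D22B = 5, SEMA3C = 5, CUL4B = 5, CLCN4 = 5, LAT = 5, ZNF304 = 5,
  ZNF674 = 5, KCTD8 = 5, CASQ1 = c(4, 7), ABLIM2 = c(4, 7),
  TTN = c(4, 7), FOXP1 = c(4, 7)
)
psamples <- c("9", "2", "5", "6", "10", "4", "7", "8")
pgenes <- names(pair_carriers)
pm <- matrix(0L, length(pgenes), length(psamples),
             dimnames = list(pgenes, psamples))
for (g in pgenes) pm[g, as.character(pair_carriers[[g]])] <- 1L
ppres <- data.frame(gene = pgenes,
                    ann[match(pgenes, ann$gene),
                        c("chrom", "pos", "ref", "alt")],
                    pm, check.names = FALSE)
names(ppres)[6:13] <- paste0("S", psamples)
write.table(ppres, file.path(out, "pair_presence_synthetic.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# sanity: pair-level counts
p1g <- sum(pm[, "2"] & (pm[, "5"] | pm[, "6"]))
p2g <- sum(pm[, "4"] & pm[, "7"])
dn5 <- sum(pm[, "5"] & !pm[, "2"])
stopifnot(p1g == 9, p2g == 6, dn5 == 9,
          sum(pm[, "6"] & !pm[, "2"]) == 0,
          sum(pm[, "7"] & !pm[, "4"]) == 0)

# ---- pedigree ----
ped_lines <- c(
  "FAM1\t1\t0\t0\t2\t2\t1\t62",
  "FAM1\t2\t0\t0\t2\t2\t1\t53",
  "FAM1\t3\t0\t0\t2\t1\t0\t65",
  "FAM1\t4\t0\t0\t2\t2\t1\t35",
  "FAM1\t5\t9\t2\t2\t2\t1\t35",
  "FAM1\t6\t9\t2\t2\t2\t1\t36",
  "FAM1\t7\t10\t4\t2\t2\t1\t35",
  "FAM1\t8\t10\t4\t1\t1\t0\t45",
  "FAM1\t9\t0\t0\t1\t1\t0\t-9",
  "FAM1\t10\t0\t0\t1\t1\t0\t-9"
)
writeLines(ped_lines, file.path(out, "family.ped"))

# ---- interval tracks ----
writeLines(c(
  "chr2\t169791753\t182991755\t2G",
  "chr4\t5149098\t8732840\t4A",
  "chr11\t16143423\t21643424\t11C",
  "chr11\t31043423\t36443424\t11E",
  "chr18\t32746001\t37246002\t18A"
), file.path(out, "fragile_sites.bed"))

sv_genes <- c("BPTF", "CACNB3", "CHCHD1", "FOXP1", "GSTK1", "ITGA1",
              "LACRT", "PHKG2", "SRA1", "CLCN4", "LAT", "KCTD8",
              "ABLIM2", "PAMR1", "TTN")
sv <- ann[match(sv_genes, ann$gene), c("chrom", "pos")]
writeLines(sprintf("%s\t%d\t%d\tsv_%02d", sv$chrom, sv$pos - 1001L,
                   sv$pos + 1000L, seq_along(sv_genes)),
           file.path(out, "structural_variation_synthetic.bed"))

rep_genes <- c("ZNF304", "ZNF674")
rp <- ann[match(rep_genes, ann$gene), c("chrom", "pos")]
writeLines(sprintf("%s\t%d\t%d\tsynthetic_repeat_%d", rp$chrom,
                   rp$pos - 501L, rp$pos + 500L, seq_along(rep_genes)),
           file.path(out, "repeats_synthetic.bed"))

# ---- default config for the family fixture ----
writeLines(
'{
  "maf_threshold": 0.001,
  "sift_damaging_max": 0.05,
  "polyphen_damaging_min": 0.447,
  "kept_classes": ["nonsynonymous_SNV", "splicing", "stopgain", "stoploss"],
  "caller_mode": "intersection",
  "control_ids": ["3"],
  "recurrence_common_min": 2
}', file.path(out, "family_config.json"))

cat("fixtures written\n")
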