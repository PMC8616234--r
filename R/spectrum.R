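# Substitution-spectrum profiling of single-base substitutions, with the
# complement-collapsed six-class convention (pyrimidine reference).

.directionalClasses <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T",
                         "G>A", "G>C", "G>T", "T>A", "T>C", "T>G")
.collapsedClasses <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

# map a directional class to its pyrimidine-reference collapsed class
.collapseClass <- function(cls) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    ref <- substr(cls, 1, 1)
    alt <- substr(cls, 3, 3)
    pur <- ref %in% c("A", "G")
    ifelse(pur, paste(comp[ref], comp[alt], sep = ">"),
           paste(ref, alt, sep = ">"))
}

#' Per-sample substitution spectrum
#'
#' Counts single-base substitutions per sample over the 12 directional
#' classes and the 6 complement-collapsed classes (C>A, C>G, C>T, T>A, T>C,
#' T>G; purine-reference substitutions are complemented, so A>G counts into
#' T>C). Indels are excluded from the substitution classes; all variants are
#' additionally tallied by variant type (SNP, DNP, TNP, indel).
#'
#' @param variants data.frame with \code{sample_id}, \code{ref}, \code{alt}.
#' @return A list with \code{directional} (samples x 12 matrix),
#'   \code{collapsed} (samples x 6 matrix), \code{cohortMedian} (median of
#'   the collapsed counts per class across samples) and \code{variantType}
#'   (samples x 4 matrix: SNP, DNP, TNP, indel).
#' @examples
#' v <- data.frame(sample_id = "S1", ref = c("A", "T"), alt = c("G", "C"))
#' substitutionSpectrum(v)$collapsed[, "T>C"]  # both collapse to T>C
#' @export
substitutionSpectrum <- function(variants) {
    .requireColumns(variants, c("sample_id", "ref", "alt"), "variant table")
    samples <- sort(unique(variants$sample_id))
    ns <- length(samples)
    directional <- matrix(0L, ns, 12L,
                          dimnames = list(samples, .directionalClasses))
    collapsed <- matrix(0L, ns, 6L,
                        dimnames = list(samples, .collapsedClasses))
    vtype <- matrix(0L, ns, 4L,
                    dimnames = list(samples,
                                    c("SNP", "DNP", "TNP", "indel")))
    if (nrow(variants)) {
        refLen <- nchar(variants$ref)
        altLen <- nchar(variants$alt)
        type <- ifelse(refLen != altLen, "indel",
                       ifelse(refLen == 1L, "SNP",
                              ifelse(refLen == 2L, "DNP",
                                     ifelse(refLen == 3L, "TNP", "MNP"))))
        tt <- table(variants$sample_id, factor(type,
            levels = c("SNP", "DNP", "TNP", "indel")))
        vtype[rownames(tt), ] <- as.matrix(tt)

        sbs <- type == "SNP" &
            variants$ref %in% c("A", "C", "G", "T") &
            variants$alt %in% c("A", "C", "G", "T")
        if (any(sbs)) {
            cls <- paste(variants$ref[sbs], variants$alt[sbs], sep = ">")
            td <- table(variants$sample_id[sbs],
                        factor(cls, levels = .directionalClasses))
            directional[rownames(td), ] <- as.matrix(td)
            tc <- table(variants$sample_id[sbs],
                        factor(.collapseClass(cls),
                               levels = .collapsedClasses))
            collapsed[rownames(tc), ] <- as.matrix(tc)
        }
    }
    list(directional = directional, collapsed = collapsed,
         cohortMedian = apply(collapsed, 2L, median),
         variantType = vtype)
}
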