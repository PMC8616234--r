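# internal helpers shared across modules

.requireColumns <- function(df, cols, what = "table") {
    missing <- setdiff(cols, colnames(df))
    if (length(missing))
        stop(sprintf("%s is missing required column(s): %s", what,
                     paste(missing, collapse = ", ")), call. = FALSE)
    invisible(TRUE)
}

# unordered pair key "A+B"
.pairKey <- function(a, b) {
    ifelse(a < b, paste(a, b, sep = "+"), paste(b, a, sep = "+"))
}

.asCountMatrix <- function(x) {
    if (is(x, "SummarizedExperiment"))
        x <- SummarizedExperiment::assay(x)
    m <- as.matrix(x)
    if (any(m < 0)) stop("counts must be non-negative", call. = FALSE)
    m
}

# reverse complement for plain base strings (used by the spectrum symmetry)
.revComp <- function(x) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    vapply(strsplit(x, ""), function(b)
        paste(rev(unname(comp[b])), collapse = ""), character(1))
}
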