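#' Median-of-ratios size factors for a count matrix
#'
#' For each sample j, the size factor is the median over genes of the ratio
#' of the sample's count to a pseudo-reference count, the geometric mean of
#' that gene's counts across all samples:
#' \deqn{\hat{s}_j = \mathrm{median}_i \; k_{ij} / (\prod_v k_{iv})^{1/m}.}
#' Genes with a zero count in any sample are excluded (their geometric mean
#' is zero, leaving the ratio undefined). Compared to total-count ratios,
#' the median makes the estimate robust against a few highly expressed,
#' strongly differential genes.
#'
#' @param counts matrix of non-negative integer counts (genes x samples).
#' @return named numeric vector of strictly positive size factors.
#' @examples
#' k <- matrix(c(1, 4, 9, 2, 8, 18), nrow = 3)
#' estimateSizeFactorsForMatrix(k)  # 1/sqrt(2), sqrt(2)
#' @export
estimateSizeFactorsForMatrix <- function(counts) {
    counts <- as.matrix(counts)
    if (ncol(counts) < 1 || nrow(counts) < 1)
        stop("need at least one gene and one sample")
    logGeoMeans <- rowMeans(log(counts))
    eligible <- is.finite(logGeoMeans)
    if (!any(eligible))
        stop("no gene has strictly positive counts in every sample; ",
             "supply size factors manually (sizeFactors<-)")
    sf <- apply(counts, 2, function(k)
        exp(median(log(k[eligible]) - logGeoMeans[eligible])))
    if (any(!is.finite(sf) | sf <= 0))
        stop("internal error: non-positive or non-finite size factor")
    setNames(sf, colnames(counts))
}

#' @describeIn estimateSizeFactorsForMatrix method for
#'   \linkS4class{CountDataSet}: estimates and stores the factors.
#' @param object a \linkS4class{CountDataSet}.
#' @export
setMethod("estimateSizeFactors", "CountDataSet", function(object) {
    sizeFactors(object) <- estimateSizeFactorsForMatrix(counts(object))
    object
})

#' Counts on the common scale
#'
#' Divides each sample's counts by its size factor, making samples sequenced
#' to different depths comparable.
#'
#' @param object a \linkS4class{CountDataSet} with size factors, or a count
#'   matrix.
#' @param sf size factors (taken from the object when omitted).
#' @return numeric matrix with entry (i, j) equal to k_ij / s_j.
#' @export
commonScale <- function(object, sf = NULL) {
    if (is(object, "CountDataSet")) {
        if (is.null(sf)) sf <- sizeFactors(object)
        k <- counts(object)
    } else k <- as.matrix(object)
    if (is.null(sf))
        stop("size factors not available; run estimateSizeFactors() first")
    if (length(sf) != ncol(k))
        stop("size factors must cover all samples")
    sweep(k, 2, sf, "/")
}

#' Write size factors as a two-column TSV (sample, factor)
#' @param sf named numeric vector (or a \linkS4class{CountDataSet}).
#' @param path output path.
#' @export
writeSizeFactors <- function(sf, path) {
    if (is(sf, "CountDataSet")) sf <- sizeFactors(sf)
    write.table(
        data.frame(sample = names(sf),
                   factor = format(sf, digits = 15, trim = TRUE)),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read size factors from a two-column TSV (sample, factor)
#' @param path input path.
#' @return named numeric vector.
#' @export
readSizeFactors <- function(path) {
    df <- read.delim(path, header = TRUE, sep = "\t", quote = "")
    setNames(as.numeric(df[[2]]), df[[1]])
}
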