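#' @rdname SampleMap-class
#' @param x an object.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname SampleMap-class
#' @export
setGeneric("barcodeLength", function(x) standardGeneric("barcodeLength"))

#' @rdname SampleOTUTable-class
#' @param x an object.
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname SampleOTUTable-class
#' @export
setGeneric("otuRecords", function(x) standardGeneric("otuRecords"))

#' @rdname SampleOTUTable-class
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))

#' @rdname SampleOTUTable-class
#' @export
setGeneric("abundanceThreshold",
           function(x) standardGeneric("abundanceThreshold"))

#' @rdname TrimmedReferenceSet-class
#' @param x an object.
#' @export
setGeneric("refFragments", function(x) standardGeneric("refFragments"))

#' @rdname TrimmedReferenceSet-class
#' @export
setGeneric("readLength", function(x) standardGeneric("readLength"))

#' @rdname TrimmedReferenceSet-class
#' @export
setGeneric("rejectedRefs", function(x) standardGeneric("rejectedRefs"))

#' @rdname HitProfile-class
#' @param x an object.
#' @param level identity threshold level.
#' @export
setGeneric("hitsAtLevel", function(x, level) standardGeneric("hitsAtLevel"))

#' @rdname HitProfile-class
#' @export
setGeneric("identityLevels", function(x) standardGeneric("identityLevels"))

#' @rdname TaxProfile-class
#' @param x an object.
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname TaxProfile-class
#' @export
setGeneric("profileRank", function(x) standardGeneric("profileRank"))

#' @rdname MockDesign-class
#' @param x an object.
#' @export
setGeneric("designMembers", function(x) standardGeneric("designMembers"))
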