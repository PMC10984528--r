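# Extract a branch of an MFB module as a standalone module sharing the same
# weights (used for ablation-style comparisons).
mfb_sub <- function(mfb, which) {
  sub <- if (which == "le") {
    le_branch(mfb$meta$cin, mfb$meta$width)
  } else {
    erf_branch(mfb$meta$cin, mfb$meta$width)
  }
  for (nm in names(sub$params)) {
    sub$params[[nm]]$v <- mfb$params[[paste0(which, ".", nm)]]$v
  }
  sub
}

# Copy every parameter value of module/model `src` into `dst` where names
# match (dst may have extra parameters, which are left untouched).
copy_params <- function(dst, src) {
  for (nm in intersect(names(dst$params), names(src$params))) {
    dst$params[[nm]]$v <- src$params[[nm]]$v
  }
  invisible(dst)
}
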