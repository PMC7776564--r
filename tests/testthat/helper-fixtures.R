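# shared fixtures, built in code

flat_elevated_spec <- function(elevated = c("9/T3", "T3/10"), factor = 1.5,
                               base = 100, ...) {
  ii <- stats::setNames(rep(base, 16), names(image_spec()$interface_intensity))
  ii[elevated] <- base * factor
  image_spec(interface_intensity = ii, ...)
}

bimodal_mix <- function(kappa = 2) {
  circular_mixture(c(100, 280), kappas = kappa, weights = c(0.5, 0.5))
}

# letters of groups `a` share no letter with groups `b`
letters_isolated <- function(letters_df, a) {
  el <- letters_df$letters[letters_df$interface_id %in% a]
  oth <- letters_df$letters[!letters_df$interface_id %in% a]
  chars <- unique(strsplit(paste(el, collapse = ""), "")[[1]])
  !any(vapply(chars, function(ch) any(grepl(ch, oth, fixed = TRUE)),
              logical(1)))
}
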