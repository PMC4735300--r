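.onLoad <- function(libname, pkgname) {
  register_fitness("nn_pos_auc", fitness_nn_pos_auc)
  register_fitness("moderated_fisher", fitness_moderated_fisher)
}
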