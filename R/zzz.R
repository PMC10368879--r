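.onLoad <- function(libname, pkgname) {
  # built-in model adapters; external adapters (e.g. transformer
  # fine-tuners) can be added with register_model() at run time
  register_model("svm",
                 function(dataset, train_cfg, ...) train_svm(dataset, train_cfg, ...),
                 predict_candidates)
  register_model("cnn",
                 function(dataset, train_cfg, ...) train_cnn(dataset, train_cfg, ...),
                 predict_candidates)
  register_model("bilstm",
                 function(dataset, train_cfg, ...) train_bilstm(dataset, train_cfg, ...),
                 predict_candidates)
  invisible()
}
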