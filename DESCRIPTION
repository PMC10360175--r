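Package: adaptaug
Title: Adaptive Image Augmentation Policy Learning for Leaf-Rust Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A deep Q-learning framework that learns an image-conditional data
    augmentation policy for semantic segmentation of leaf rust. Each image in a
    training vector is described by twelve geometric and colour features; an
    agent selects one of eight augmentation actions per image, the augmented
    set is used to fine-tune a pre-trained segmentation model, and the change
    in a Dice-style score over a fixed test set is returned as the reward.
    Ships a synthetic leaf/rust image generator, the eight-action augmentation
    registry, confusion-matrix segmentation metrics, a fast pixel-wise
    surrogate segmentation backend with snapshot/restore semantics, the
    reinforcement-learning environment, and a from-scratch DQN agent with
    experience replay and a target network.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
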