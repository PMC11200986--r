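# Keypoint sentence templates: one {kp} slot per template.
# prefix: keypoint name at the end; intermediate: mid-sentence; suffix: leading.
prefix:
  - "a photo of the {kp}"
  - "a close-up photo of an animal's {kp}"
  - "an image showing the {kp}"
intermediate:
  - "the {kp} is a key point of the animal body"
  - "locate the {kp} on the animal in the photo"
  - "this animal's {kp} appears in the image"
suffix:
  - "{kp}, a joint location on an animal"
  - "{kp} of the animal in the picture"
  - "{kp}, an anatomical landmark of the animal"
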