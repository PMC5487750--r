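{
  "schema_version": "1.0",
  "image_id": "fixture-01",
  "jugulum": [200, 50],
  "nipple_left": [120.5, 180.25],
  "nipple_right": [280.5, 184],
  "border_left": [
    [120, 120],
    [160, 140],
    [170, 185],
    [150, 230],
    [120, 245],
    [85, 230],
    [70, 185],
    [80, 140]
  ],
  "border_right": [
    [280, 122],
    [320, 142],
    [335, 187],
    [325, 232],
    [280, 246],
    [245, 232],
    [230, 187],
    [240, 142]
  ]
}
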