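# Weekly 8-item pain-interference short form: eight digits 0-4, one per item.
template_id: promis8
kind: digit_vector
item_count: 8
item_range: [0, 4]
valid_example: "01324101"
description: Weekly 8-item pain interference scale (0-4 per item)
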