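# Daily school attendance: one two-character code.
template_id: attendance
kind: code_choice
code_options: [WD, AM, AF, AW]
valid_example: WD
description: Daily school attendance report
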