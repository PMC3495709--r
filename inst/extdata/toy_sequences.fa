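>gluA
MSTKLVEQWRNDAGLPFYTTCHAIEKGDLVR
>gluB
MSTKLVEQWRNDAGLPFYTCHAIEKGDLVR
>gluC
MSTKLIEQWRNDAALPFYTTCHAVEKGDLVR
>gluD
MATKLVEQWRDDAGLPFYTTCHAIEKGELVR
>gluE
MSTKLVEQWRNDAGQQQLPFYTTCHAIEKGDLVR
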