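fa^114^da^180^GFECBAfa^33^f^3^a^2^fa^59^hKJBAfa^144^ga^3^ga^15^ga^6^ga^4^ga^5^ga^39^bebea^12^hea^7^hea^18^hea^7^hea^17^hea^7^bea^239^bFEDCBAfa^223^ga^3^ga^5^da^10^d^4^a^10^dada^127^b_LINE_ca^133^GEDCBAfa^21^hKJ
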