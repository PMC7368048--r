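>AMELX_SYNTH synthetic stand-in for the X-isoform of human amelogenin (not the UniProt sequence)
MGPWILLTCLLGAAFSMPLPPHPGHPGYINFSYEVLTPLKWYQNMIRHPYPSYGYEPMGG
WLHHQIIPVLSQQHPPSHTLQPHHHLPVVPAQQPVIPQQPMMPVPGQHSMTPIQHHQPNL
PPSAQQPFQPQPVQPQPHQPMQPQPPVHPMQPLPPQPPLPPMFPMQPLPPMLPDLTLEAW
PSTDKTKREEVD
>AMELY_SYNTH synthetic stand-in for the Y-isoform of human amelogenin (not the UniProt sequence)
MGPWILLTCLLGAAFSMPLPPHPGHPGYINFSYEALTPLKWYQSMIRQPYPSYGYEPMGG
WLHHQIIPVLSQQHPPSHTLQPHHHLPVVPSQQPVIPRQPLMPFPGQHSMTPIQHHQPNL
PPSAQQPFQPQPVQPQPHQPMQPQPPIHPLQSLPPQAPLPPVFSMQPLPPMLPDLTLEAW
PSTDKTKREEVD
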