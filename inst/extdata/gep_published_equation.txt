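1/(TEIZP - NFA) + sin(sin(TEIZP) + (MECN - MECN))/(MRCH - MCIHN)*sin(MRCH) + ZXS*1/(MRCH*sin(ZXS)/ZXS + ZXS/TEIZP + sin(sin(sin(sin(MRCH)*sin(MCIHN)))))
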