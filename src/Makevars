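# FFTW3 ships with the R installation prefix; fall back to pkg-config if not.
FFTW_PREFIX = $(R_HOME)/../..
PKG_CPPFLAGS = -I$(FFTW_PREFIX)/include
PKG_LIBS = -L$(FFTW_PREFIX)/lib -Wl,-rpath,$(FFTW_PREFIX)/lib -lfftw3 -lfftw3f
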